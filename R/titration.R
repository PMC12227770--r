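## Titration of the Adams value: occupancy scans, logistic fits on the B and
## log-concentration scales, and aggregation over repeats into K_D and dG.

#' Run a GCNCMC titration
#'
#' Runs one independent chain per (B value, repeat) from a fresh copy of the
#' initial state and records the mean region occupancy over
#' post-equilibration cycles. Chains that error are flagged and excluded
#' from fitting. Each chain gets a deterministic seed derived from
#' \code{seed}, distinct per (B, repeat).
#'
#' @param state Initial \linkS4class{SystemState}, or a list of states
#'   cycled over repeats (e.g. an empty and a saturated start, so that
#'   equilibration transients cancel across repeats).
#' @param region A \linkS4class{GCMCRegion}.
#' @param schedule A \linkS4class{ChainSchedule} (its movePattern must name
#'   exactly one species).
#' @param protocol \linkS4class{NCMCProtocol} for the titrated species.
#' @param bValues Numeric vector of Adams values to scan.
#' @param repeats Number of independent repeats per B value.
#' @param seed Base seed for the per-chain streams.
#' @return Occupancy table: data.frame with columns b, repeatId, occupancy,
#'   nCycles, failed.
#' @export
runTitration <- function(state, region, schedule, protocol, bValues,
                         repeats = 4, seed = 1) {
  species <- unique(schedule@movePattern)
  stopifnot(length(species) == 1L, length(bValues) >= 1L)
  starts <- if (is.list(state) && !is(state, "SystemState")) state else
    list(state)
  rows <- vector("list", length(bValues) * repeats)
  n <- 0L
  for (r in seq_len(repeats)) {
    start <- starts[[(r - 1L) %% length(starts) + 1L]]
    for (ib in seq_along(bValues)) {
      set.seed(childSeed(seed, r, ib))
      n <- n + 1L
      res <- tryCatch(
        runChain(start, region, schedule,
                 stats::setNames(list(protocol), species),
                 stats::setNames(bValues[ib], species)),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warning("chain failed at B = ", bValues[ib], " repeat ", r, ": ",
                conditionMessage(res))
        rows[[n]] <- data.frame(
          b = bValues[ib], repeatId = r, occupancy = NA_real_,
          nCycles = 0L, failed = TRUE
        )
        next
      }
      post <- res$occupancy$cycle > schedule@nEquil
      occ <- mean(res$occupancy[post, species])
      rows[[n]] <- data.frame(
        b = bValues[ib], repeatId = r, occupancy = occ,
        nCycles = sum(post), failed = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

## Initial B50 guess: linear interpolation of the first 0.5 crossing.
.b50Init <- function(b, occ) {
  o <- order(b)
  b <- b[o]; occ <- occ[o]
  above <- which(occ >= 0.5)
  if (!length(above)) return(max(b))
  i <- above[1]
  if (i == 1L) return(min(b))
  b[i - 1] + (0.5 - occ[i - 1]) / (occ[i] - occ[i - 1]) * (b[i] - b[i - 1])
}

#' Fit the occupancy logistic on the Adams-value scale
#'
#' Fits N(B) = 1 / (1 + exp(k (B50 - B))) per repeat by nonlinear least
#' squares. B50 is bounded within the scanned range extended by one range
#' width; k is constrained positive. Repeats with degenerate data (all empty
#' or all saturated) are reported as failed.
#'
#' @param table Occupancy table from \code{\link{runTitration}} (columns b,
#'   repeatId, occupancy; flagged rows are dropped).
#' @return data.frame with columns repeatId, b50, k, converged.
#' @export
fitBScale <- function(table) {
  tab <- table[!is.na(table$occupancy) & !isTRUE(table$failed), , drop = FALSE]
  if ("failed" %in% names(tab)) tab <- tab[!tab$failed, , drop = FALSE]
  reps <- sort(unique(tab$repeatId))
  out <- lapply(reps, function(r) {
    d <- tab[tab$repeatId == r, ]
    if (length(unique(d$b)) < 4L) {
      warning("repeat ", r, ": need >= 4 distinct B values")
      return(data.frame(repeatId = r, b50 = NA_real_, k = NA_real_,
                        converged = FALSE))
    }
    rng <- diff(range(d$b))
    if (all(d$occupancy < 0.05) || all(d$occupancy > 0.95)) {
      warning("repeat ", r, ": degenerate occupancy data, fit skipped")
      return(data.frame(repeatId = r, b50 = NA_real_, k = NA_real_,
                        converged = FALSE))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        occupancy ~ 1 / (1 + exp(k * (b50 - b))),
        data = d,
        start = list(b50 = .b50Init(d$b, d$occupancy), k = 1),
        lower = c(min(d$b) - rng, 1e-6),
        upper = c(max(d$b) + rng, 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning("repeat ", r, ": fit failed: ", conditionMessage(fit))
      return(data.frame(repeatId = r, b50 = NA_real_, k = NA_real_,
                        converged = FALSE))
    }
    co <- stats::coef(fit)
    data.frame(repeatId = r, b50 = unname(co["b50"]), k = unname(co["k"]),
               converged = TRUE)
  })
  do.call(rbind, out)
}

#' Fit the occupancy logistic on the log-concentration scale
#'
#' Maps each B to log10(c) via \code{\link{concentrationFromB}} and fits
#' N(log10 c) = 1 / (1 + exp(k (log10 K_D - log10 c))). This is an exact
#' reparameterisation of the B-scale fit (B is linear in ln c), so the K_D
#' agrees with \code{\link{kdFromB50}} applied to the B-scale fit of the
#' same data.
#'
#' @param table Occupancy table from \code{\link{runTitration}}.
#' @param spec An \linkS4class{AdamsSpec} for the B-to-concentration map.
#' @return data.frame with columns repeatId, kd, k, converged.
#' @export
fitLogcScale <- function(table, spec) {
  tab <- table
  tab$b <- log10(concentrationFromB(spec, table$b))
  fits <- fitBScale(tab)
  data.frame(
    repeatId = fits$repeatId,
    kd = 10^fits$b50,
    k = fits$k,
    converged = fits$converged
  )
}

#' Aggregate per-repeat titration fits
#'
#' Converts each repeat's B50 to a dissociation constant, averages K_D over
#' repeats (mean and standard error of the mean), and derives the standard
#' binding free energy from the mean K_D; the K_D error propagates to dG by
#' the delta method. Kendall tau concordance of occupancy with B is computed
#' across all occupancy rows of all repeats.
#'
#' @param fits Per-repeat fits from \code{\link{fitBScale}}.
#' @param spec An \linkS4class{AdamsSpec}.
#' @param table The occupancy table used for the fits (for Kendall tau).
#' @return A \linkS4class{TitrationFit}.
#' @export
aggregateTitration <- function(fits, spec, table) {
  ok <- fits[fits$converged, , drop = FALSE]
  if (nrow(ok) < 1L) stop("no successful repeats to aggregate")
  if (nrow(ok) < 2L) {
    warning("single successful repeat: standard errors undefined")
  }
  kd <- kdFromB50(spec, ok$b50)
  nOk <- nrow(ok)
  kdMean <- mean(kd)
  kdSe <- if (nOk > 1) stats::sd(kd) / sqrt(nOk) else NA_real_
  b50Mean <- mean(ok$b50)
  b50Se <- if (nOk > 1) stats::sd(ok$b50) / sqrt(nOk) else NA_real_
  dg <- dgFromKd(kdMean, spec@temperature, spec@cStandard)
  dgSe <- if (is.na(kdSe)) NA_real_ else kT(spec@temperature) * kdSe / kdMean
  tabOk <- table[!is.na(table$occupancy), , drop = FALSE]
  tau <- suppressWarnings(
    stats::cor(tabOk$b, tabOk$occupancy, method = "kendall")
  )
  new("TitrationFit",
    b50 = b50Mean, b50Se = b50Se, k = mean(ok$k), kd = kdMean, kdSe = kdSe,
    dg = dg, dgSe = dgSe, kendallTau = tau,
    perRepeat = data.frame(repeatId = ok$repeatId, b50 = ok$b50, k = ok$k,
                           kd = kd)
  )
}

#' Deterministic child seed
#'
#' Derives a reproducible 31-bit seed from a base seed and two indices, so
#' that every chain of a titration gets its own stream.
#'
#' @param seed Base seed.
#' @param i,j Indices (e.g. repeat and B-value index).
#' @return Integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, i, j = 0) {
  s <- (as.numeric(seed) * 48271 + i * 100003 + j * 1009) %% 2147483646
  as.integer(s) + 1L
}

#' Plot a titration curve with its fitted logistic
#'
#' Draws occupancy against the Adams value for every repeat, overlays the
#' aggregated logistic fit and marks B50, writing a PNG.
#'
#' @param table Occupancy table from \code{\link{runTitration}}.
#' @param fit A \linkS4class{TitrationFit}.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
plotTitration <- function(table, fit, path) {
  tab <- table[!is.na(table$occupancy), , drop = FALSE]
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  plot(tab$b, tab$occupancy, pch = 19,
       col = tab$repeatId, xlab = "Adams value B",
       ylab = "mean occupancy N(B)",
       main = sprintf("B50 = %.2f +/- %.2f, K_D = %.3g M",
                      fit@b50, fit@b50Se, fit@kd))
  bb <- seq(min(tab$b), max(tab$b), length.out = 200)
  graphics::lines(bb, 1 / (1 + exp(fit@k * (fit@b50 - bb))), lwd = 2)
  graphics::abline(v = fit@b50, lty = 2)
  graphics::abline(h = 0.5, lty = 3)
  invisible(path)
}
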