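#' Weighted histogram analysis method (WHAM)
#'
#' Combines biased umbrella-window histograms into one unbiased potential
#' of mean force by self-consistent iteration over the window free-energy
#' shifts f_i:
#'
#'   p(b) = sum_i n_i(b) / sum_i N_i exp(beta (f_i - u_i(z_b)))
#'   f_i  = -kT log sum_b p(b) exp(-beta u_i(z_b))
#'
#' with u_i the harmonic bias of window i. Iteration stops when
#' max |delta f_i| < `tol` or after `max_iter` sweeps; a non-converged
#' result is returned flagged, with the final residual. The PMF is
#' -kT log p(b), shifted so the bulk reference region (bins within the
#' outermost `bulk_fraction` of the sampled coordinate range, by default
#' the top 10 percent) averages zero; `reference = "min"` shifts the
#' minimum to zero instead. Per-bin uncertainty comes from `n_boot`
#' bootstrap resamples of each window's samples.
#'
#' @param windows List of sampled [umbrella_window()] objects (k = 0 means
#'   unbiased). Windows flagged failed or empty are rejected.
#' @param temperature Temperature (K).
#' @param n_bins Number of histogram bins over the sampled range.
#' @param tol Convergence tolerance on the f_i (kJ/mol).
#' @param max_iter Maximum self-consistency iterations.
#' @param n_boot Bootstrap resamples for per-bin standard errors (0 = none).
#' @param reference `"bulk"` or `"min"`.
#' @param bulk_fraction Fraction of the upper coordinate range treated as
#'   bulk when `reference = "bulk"`.
#' @param min_overlap Adjacent windows sharing fewer than this many
#'   samples in common occupied bins trigger a warning; zero overlap is an
#'   error naming the gap.
#' @return Object of class `pmf_profile`: list with `z` (bin centres),
#'   `pmf` (kJ/mol, NA on empty bins), `counts`, `se` (if bootstrapped),
#'   `f` (window shifts), `iterations`, `residual`, `converged`,
#'   `temperature`, `reference`.
#' @export
wham <- function(windows, temperature = 300, n_bins = 200, tol = 1e-7,
                 max_iter = 1e5, n_boot = 50, reference = c("bulk", "min"),
                 bulk_fraction = 0.1, min_overlap = 10) {
  reference <- match.arg(reference)
  windows <- Filter(function(w) !isTRUE(w$failed), windows)
  if (length(windows) == 0) stop("no usable windows")
  ns <- vapply(windows, function(w) length(w$samples), integer(1))
  if (any(ns == 0)) stop("window(s) without samples: ",
                         paste(which(ns == 0), collapse = ", "))

  all_s <- unlist(lapply(windows, `[[`, "samples"))
  rng <- range(all_s)
  if (diff(rng) <= 0) stop("degenerate sampling range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  z <- (edges[-1] + edges[-length(edges)]) / 2

  counts <- vapply(windows, function(w) {
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins)
  }, integer(n_bins))                      # n_bins x n_win
  check_window_overlap(windows, counts, min_overlap)

  fit <- wham_iterate(counts, z, windows, temperature, tol, max_iter)
  pmf <- shift_pmf(fit$pmf, z, rowSums(counts), reference, bulk_fraction)

  se <- NULL
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_bins, n_boot)
    for (b in seq_len(n_boot)) {
      cb <- vapply(windows, function(w) {
        s <- w$samples[sample.int(length(w$samples), replace = TRUE)]
        tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
      }, integer(n_bins))
      fb <- wham_iterate(cb, z, windows, temperature,
                         tol = max(tol, 1e-6), max_iter = max_iter,
                         f_init = fit$f)
      boot[, b] <- shift_pmf(fb$pmf, z, rowSums(cb), reference, bulk_fraction)
    }
    se <- apply(boot, 1, stats::sd, na.rm = TRUE)
  }

  structure(list(z = z, pmf = pmf, counts = rowSums(counts), se = se,
                 f = fit$f, iterations = fit$iterations,
                 residual = fit$residual, converged = fit$converged,
                 temperature = temperature, reference = reference,
                 bulk_fraction = bulk_fraction),
            class = "pmf_profile")
}

# self-consistent WHAM iteration (log-space, numerically stable)
wham_iterate <- function(counts, z, windows, temperature, tol, max_iter,
                         f_init = NULL) {
  kT <- KB * temperature
  beta <- 1 / kT
  n_bins <- nrow(counts); n_win <- ncol(counts)
  N <- colSums(counts)
  H <- rowSums(counts)
  # bias energies u[b, i]
  u <- vapply(seq_len(n_win), function(i) {
    bias_energy(z, windows[[i]]$d0, windows[[i]]$k)
  }, numeric(n_bins))
  f <- f_init %||% numeric(n_win)
  logN <- log(N)
  logH <- ifelse(H > 0, log(H), -Inf)
  occupied <- H > 0
  residual <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    # log denominator per bin: logsumexp_i [ log N_i + beta f_i - beta u_bi ]
    M <- sweep(-beta * u, 2, logN + beta * f, `+`)
    mx <- apply(M, 1, max)
    logden <- mx + log(rowSums(exp(M - mx)))
    logp <- logH - logden
    logp[!occupied] <- -Inf
    # f update: f_i = -kT logsumexp_b [ logp_b - beta u_bi ]
    Mi <- logp - beta * u                    # recycles logp down columns
    mxi <- apply(Mi, 2, max)
    f_new <- -kT * (mxi + log(colSums(exp(sweep(Mi, 2, mxi, `-`)))))
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual < tol) break
  }
  pmf <- -kT * (logp - max(logp[occupied]))
  pmf[!occupied] <- NA_real_
  conv <- residual < tol
  if (!conv) {
    warning("WHAM did not converge: residual ", signif(residual, 4),
            " kJ/mol after ", it, " iterations")
  }
  list(pmf = pmf, f = f, iterations = it, residual = residual,
       converged = conv)
}

shift_pmf <- function(pmf, z, H, reference, bulk_fraction) {
  ok <- is.finite(pmf) & H > 0
  if (!any(ok)) stop("all-empty profile")
  if (reference == "bulk") {
    zmax <- max(z[ok]); zmin <- min(z[ok])
    bulk <- ok & z >= zmax - bulk_fraction * (zmax - zmin)
    pmf - mean(pmf[bulk])
  } else {
    pmf - min(pmf[ok])
  }
}

check_window_overlap <- function(windows, counts, min_overlap) {
  n_win <- ncol(counts)
  if (n_win < 2) return(invisible())
  ord <- order(vapply(windows, `[[`, numeric(1), "d0"))
  for (j in seq_len(n_win - 1)) {
    a <- counts[, ord[j]]; b <- counts[, ord[j + 1]]
    shared <- sum(pmin(a, b)[a > 0 & b > 0])
    if (shared == 0) {
      stop("no histogram overlap between windows d0 = ",
           windows[[ord[j]]]$d0, " and d0 = ", windows[[ord[j + 1]]]$d0)
    }
    if (shared < min_overlap) {
      warning("weak histogram overlap (", shared, " shared samples) between ",
              "windows d0 = ", windows[[ord[j]]]$d0, " and d0 = ",
              windows[[ord[j + 1]]]$d0)
    }
  }
  invisible()
}

#' Locate the PMF minimum
#'
#' Finds the bin of minimal free energy, refines it by a parabolic fit
#' through the bin and its two neighbours, and reports the well depth
#' relative to the profile's reference (zero level). Ties break toward
#' smaller z. Sparsely occupied tail bins are excluded (a "minimum" held
#' up by a handful of correlated excursions is histogram noise, not a
#' well): a bin must carry at least `min_counts` samples, by default the
#' larger of 10 and 2 percent of the best-sampled bin's count.
#' A profile whose total variation is within the noise level is flagged
#' degenerate.
#'
#' @param profile A `pmf_profile`.
#' @param min_counts Minimum per-bin sample count for a bin to be
#'   considered; `NULL` (default) uses `max(10, 0.02 * max(counts))`.
#' @return List with `z_min` (nm), `depth` (kJ/mol, positive for a well),
#'   `degenerate` flag.
#' @export
pmf_minimum <- function(profile, min_counts = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  min_counts <- min_counts %||% max(10, 0.02 * max(profile$counts))
  ok <- which(is.finite(profile$pmf) & profile$counts >= min_counts)
  if (length(ok) < 3) ok <- which(is.finite(profile$pmf))
  if (length(ok) < 3) stop("profile must be finite on at least 3 bins")
  pmf <- profile$pmf; z <- profile$z
  i <- ok[which.min(pmf[ok])]   # which.min takes the first (smallest z) tie
  z_min <- z[i]
  # parabolic refinement when both neighbours are finite interior bins
  if (i > 1 && i < length(pmf) && is.finite(pmf[i - 1]) && is.finite(pmf[i + 1])) {
    y1 <- pmf[i - 1]; y2 <- pmf[i]; y3 <- pmf[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) {
      z_min <- z[i] + 0.5 * (y1 - y3) / denom * (z[2] - z[1])
    }
  }
  depth <- -pmf[i]
  noise <- if (!is.null(profile$se)) 3 * stats::median(profile$se, na.rm = TRUE) else 1e-8
  degenerate <- (max(pmf[ok]) - min(pmf[ok])) <= max(noise, 1e-8)
  list(z_min = z_min, depth = depth, degenerate = degenerate)
}

#' Difference of two PMF well depths
#'
#' `depth(a) - depth(b)` with bootstrap uncertainties combined in
#' quadrature. Each depth is evaluated on its profile's own grid (a well
#' depth needs no common binning), so the difference is exactly
#' antisymmetric; profiles over disjoint reaction-coordinate ranges are
#' rejected as incomparable.
#'
#' @param a,b `pmf_profile` objects.
#' @return List with `difference` (kJ/mol), `se`, and the two minima.
#' @export
pmf_difference <- function(a, b) {
  stopifnot(inherits(a, "pmf_profile"), inherits(b, "pmf_profile"))
  if (max(b$z) < min(a$z) || min(b$z) > max(a$z)) {
    stop("disjoint reaction-coordinate grids")
  }
  ma <- pmf_minimum(a); mb <- pmf_minimum(b)
  se_at <- function(p, zm) {
    if (is.null(p$se)) return(NA_real_)
    p$se[which.min(abs(p$z - zm))]
  }
  se <- sqrt(sum(c(se_at(a, ma$z_min), se_at(b, mb$z_min))^2))
  list(difference = ma$depth - mb$depth, se = se, min_a = ma, min_b = mb)
}

#' Write a PMF profile as TSV
#'
#' Columns: z (nm), pmf (kJ/mol), se, counts.
#' @param profile A `pmf_profile`.
#' @param path Output file.
#' @export
write_pmf <- function(profile, path) {
  utils::write.table(
    data.frame(z = profile$z, pmf = profile$pmf,
               se = profile$se %||% NA_real_, counts = profile$counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$pmf)
  cat(sprintf(
    "PMF profile: %d bins over [%.3f, %.3f] nm, %s after %d iterations (residual %.2g)\n",
    length(x$z), min(x$z), max(x$z),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual))
  m <- pmf_minimum(x)
  cat(sprintf("  minimum at z = %.3f nm, well depth %.2f kJ/mol (ref: %s)\n",
              m$z_min, m$depth, x$reference))
  invisible(x)
}
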