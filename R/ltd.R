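# Lattice-translocation-defect intensity model ------------------------------
#
# Two identical lattices, offset by a fractional translation t_d and present
# with population fractions kappa and 1 - kappa, coexist in one mosaic
# block.  Observed (total) intensities are modulated relative to the
# single-lattice intensity by
#
#   f(h) = (2 kappa^2 - 2 kappa + 1) + 2 kappa (1 - kappa) cos(2 pi h . t_d)
#        = (1 - 2 kappa)^2 + 4 kappa (1 - kappa) cos^2(pi h . t_d)
#
# so f is bounded in [(1 - 2 kappa)^2, 1], equals 1 whenever h . t_d is an
# integer, and is invariant under kappa -> 1 - kappa (hence the canonical
# restriction kappa <= 1/2).

#' Define a lattice-translocation defect model
#'
#' @param t_d fractional translocation vector, three values in `[0, 1)`.
#' @param kappa minor-lattice population fraction, in `[0, 0.5]` (kappa and
#'   `1 - kappa` are indistinguishable, so the canonical half-range is
#'   enforced).
#' @return a `defect_model` list.
#' @export
defect_model <- function(t_d, kappa) {
  t_d <- as.numeric(t_d) %% 1
  if (length(t_d) != 3) abort("t_d must have three components")
  if (!is.finite(kappa) || kappa < 0 || kappa > 0.5) {
    abort("kappa must lie in [0, 0.5]; use 1 - kappa for the equivalent model")
  }
  structure(list(t_d = t_d, kappa = kappa), class = "defect_model")
}

#' @export
print.defect_model <- function(x, ...) {
  cat(sprintf("<defect_model> t_d = (%s), kappa = %.3f\n",
              paste(signif(x$t_d, 6), collapse = ", "), x$kappa))
  invisible(x)
}

# canonical representative of the t_d ~ -t_d (mod 1) equivalence
canonical_td <- function(t_d) {
  t_d <- t_d %% 1
  alt <- (-t_d) %% 1
  for (i in 1:3) {
    if (t_d[i] < alt[i]) return(t_d)
    if (t_d[i] > alt[i]) return(alt)
  }
  t_d
}

#' Intensity modulation factor of a defect model
#'
#' Evaluates the cosine modulation `f(h)` for Miller indices `h`.
#'
#' @param hkl data frame (or matrix) with columns/cols `h`, `k`, `l`.
#' @param model a [defect_model()].
#' @return numeric vector of factors in `[(1 - 2 kappa)^2, 1]`.
#' @export
correction_factor <- function(hkl, model) {
  hm <- hkl_matrix(hkl)
  k <- model$kappa
  phase <- hm %*% model$t_d
  (2 * k^2 - 2 * k + 1) + 2 * k * (1 - k) * cos(2 * pi * phase)
}

hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) {
    as.matrix(hkl[, c("h", "k", "l")])
  } else {
    m <- rbind(hkl)
    if (ncol(m) != 3) abort("hkl must have columns h, k, l")
    m
  }
}

#' Read and write reflection tables
#'
#' Plain-text reflection files with whitespace- or comma-separated columns
#' `h k l I sigma` (header optional; `sigma` optional).
#'
#' @param path file path.
#' @return tibble with columns `h`, `k`, `l`, `intensity`, `sigma`.
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) abort(paste0("no such reflection file: ", path))
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-df-z]", first)  # letters other than e (1e5 etc.)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep,
                          strip.white = TRUE)
  if (ncol(df) < 4) abort("reflection file needs at least h k l I columns")
  names(df)[1:4] <- c("h", "k", "l", "intensity")
  if (ncol(df) >= 5 && !header) names(df)[5] <- "sigma"
  if (!"sigma" %in% names(df)) df$sigma <- NA_real_
  out <- as_tibble(df[, c("h", "k", "l", "intensity", "sigma")])
  validate_reflections(out)
  out
}

validate_reflections <- function(refl) {
  if (any(refl$h == 0 & refl$k == 0 & refl$l == 0)) {
    abort("reflection (0,0,0) is not allowed")
  }
  if (anyDuplicated(refl[, c("h", "k", "l")]) > 0) {
    abort("duplicate (h,k,l) in reflection set")
  }
  if (any(!is.na(refl$sigma) & refl$sigma <= 0)) {
    abort("sigma must be > 0 where provided")
  }
  invisible(refl)
}

#' @rdname read_reflections
#' @param refl reflection tibble.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(refl, path) {
  utils::write.table(refl, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Correct observed intensities for a lattice-translocation defect
#'
#' Divides observed (total) intensities by the modulation factor `f(h)` to
#' recover per-lattice (unit) intensities; sigmas are scaled by `1/f(h)`.
#' Reflections whose factor falls below `floor` are flagged (`flagged`
#' column) rather than silently amplified: their corrected values are still
#' reported but should be treated as unreliable (noise amplification goes
#' as `1/f`).
#'
#' @param observed reflection tibble (`h`, `k`, `l`, `intensity`, `sigma`).
#' @param model a [defect_model()].
#' @param floor smallest trustworthy factor; must be positive.
#' @return tibble with corrected `intensity`/`sigma` plus `factor` and
#'   `flagged` columns.
#' @export
correct_intensities <- function(observed, model, floor = 0.05) {
  if (!is.numeric(floor) || floor <= 0) abort("floor must be > 0")
  validate_reflections(observed)
  f <- as.numeric(correction_factor(observed, model))
  out <- as_tibble(observed)
  out$factor <- f
  out$flagged <- f < floor
  out$intensity <- observed$intensity / f
  out$sigma <- observed$sigma / f
  out
}

#' Apply a defect model to unit intensities
#'
#' The forward model (inverse of [correct_intensities()]): multiplies unit
#' intensities by `f(h)`.  Used by the synthetic generator and for
#' round-trip checks.
#'
#' @inheritParams correct_intensities
#' @param unit reflection tibble of per-lattice intensities.
#' @return modulated reflection tibble.
#' @export
modulate_intensities <- function(unit, model) {
  f <- as.numeric(correction_factor(unit, model))
  out <- as_tibble(unit)
  out$intensity <- unit$intensity * f
  out$sigma <- unit$sigma * f
  out
}

#' Intensity R-factor between two reflection sets
#'
#' `sum |I_a - I_b| / sum I_a` over the common `(h,k,l)` reflections.
#'
#' @param a,b reflection tibbles.
#' @return one-row tibble: `r_factor`, `n_common`.
#' @export
intensity_r_factor <- function(a, b) {
  m <- dplyr::inner_join(as_tibble(a), as_tibble(b),
                         by = c("h", "k", "l"), suffix = c("_a", "_b"))
  if (nrow(m) == 0) abort("no common reflections between the two sets")
  tibble(r_factor = sum(abs(m$intensity_a - m$intensity_b)) /
           sum(m$intensity_a),
         n_common = nrow(m))
}

#' Default candidate translocation vectors
#'
#' All fractional vectors whose components are rationals with denominators
#' up to `max_denominator`, deduplicated over the `t_d ~ -t_d` equivalence
#' and excluding the null vector.  Translocation vectors in real crystals
#' are low-order rational, so this small menu is usually sufficient.
#'
#' @param max_denominator largest denominator per component (default 4).
#' @return list of numeric length-3 vectors.
#' @export
td_candidates <- function(max_denominator = 4) {
  fracs <- unique(unlist(lapply(1:max_denominator,
                                function(d) (0:(d - 1)) / d)))
  grid <- expand.grid(a = fracs, b = fracs, c = fracs)
  cand <- lapply(seq_len(nrow(grid)),
                 function(i) canonical_td(as.numeric(grid[i, ])))
  cand <- cand[!vapply(cand, function(v) all(v == 0), logical(1))]
  cand[!duplicated(vapply(cand, paste, character(1), collapse = ","))]
}

# Reflection-level least squares for one candidate t_d: with the scale s
# profiled out, minimising sum_i (I_i - s f(phase_i))^2 over (s, kappa) is
# maximising A(k)^2 / B(k) with A = sum_b n_b m_b f_b, B = sum_b n_b f_b^2
# (per-phase-class counts n_b and means m_b).  Scoring at reflection level,
# not bin-mean level, matters: a wrong candidate that merges phase classes
# can fit its few bin means perfectly but cannot explain the within-bin
# spread the merge creates.
fit_kappa_for_bins <- function(phase_class, intensity, kappa_grid_step) {
  cls <- round(phase_class, 6) %% 1  # snap float dust so 0.999999... == 0
  bins <- stats::aggregate(intensity, by = list(phase = cls), FUN = mean)
  cnt <- as.numeric(table(factor(cls, levels = bins$phase)))
  if (nrow(bins) < 2) return(NULL)
  cosx <- cos(2 * pi * bins$phase)
  ss_zero <- sum(intensity^2)
  explained <- function(k) {
    f <- (2 * k^2 - 2 * k + 1) + 2 * k * (1 - k) * cosx
    sum(cnt * bins$x * f)^2 / sum(cnt * f^2)
  }
  ks <- seq(0, 0.5, by = kappa_grid_step)
  ex <- vapply(ks, explained, double(1))
  k0 <- ks[which.max(ex)]
  opt <- stats::optimize(explained, c(max(0, k0 - kappa_grid_step),
                                      min(0.5, k0 + kappa_grid_step)),
                         maximum = TRUE)
  kb <- if (opt$objective > max(ex)) opt$maximum else k0
  f <- (2 * kb^2 - 2 * kb + 1) + 2 * kb * (1 - kb) * cosx
  s <- sum(cnt * bins$x * f) / sum(cnt * f^2)
  list(kappa = kb, rss = ss_zero - explained(kb),
       tss = sum((intensity - mean(intensity))^2),
       bins = tibble(phase = bins$phase, mean_intensity = bins$x,
                     n = cnt, fitted = s * f))
}

#' Estimate lattice-translocation defect parameters from intensities
#'
#' For each candidate translocation vector, reflections are binned by the
#' phase `h . t_d mod 1` and the per-bin mean intensities are fitted against
#' the modulation factor `f` by least squares over `kappa` (grid search on
#' `[0, 0.5]` followed by local refinement).  The candidate minimising the
#' residual wins.  Candidates producing a single phase class fit any
#' `kappa` equally and are skipped; if all candidates degenerate this way
#' the defect is not identifiable and an error is raised.
#'
#' @param observed reflection tibble.
#' @param candidates list of candidate fractional vectors
#'   (default [td_candidates()]).
#' @param kappa_grid_step grid resolution for the kappa search.
#' @return an `ltd_fit` object: list with `model` ([defect_model()]),
#'   `residual`, `r_squared`, `bins` (per-phase-class means for the winning
#'   candidate) and `candidates` (per-candidate diagnostics tibble).
#'   Methods: [tidy.ltd_fit()], [glance.ltd_fit()], [autoplot.ltd_fit()].
#' @export
estimate_defect <- function(observed, candidates = td_candidates(),
                            kappa_grid_step = 0.005) {
  validate_reflections(observed)
  hm <- hkl_matrix(observed)
  rows <- lapply(candidates, function(td) {
    phase <- (hm %*% td) %% 1
    fit <- fit_kappa_for_bins(phase, observed$intensity, kappa_grid_step)
    if (is.null(fit)) return(NULL)
    list(td = td, fit = fit)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    abort("defect not identifiable: every candidate gives a single phase class")
  }
  diag_tbl <- purrr::map_dfr(rows, function(r) {
    tibble(t_d = paste(signif(r$td, 6), collapse = ","),
           kappa = r$fit$kappa, rss = r$fit$rss, n_bins = nrow(r$fit$bins))
  })
  best <- rows[[which.min(diag_tbl$rss)]]
  out <- list(model = defect_model(best$td, min(best$fit$kappa,
                                                1 - best$fit$kappa)),
              residual = best$fit$rss,
              r_squared = 1 - best$fit$rss / max(best$fit$tss, 1e-300),
              bins = best$fit$bins,
              candidates = dplyr::arrange(diag_tbl, .data$rss))
  class(out) <- "ltd_fit"
  out
}

#' @export
print.ltd_fit <- function(x, ...) {
  cat(sprintf(
    "<ltd_fit> t_d = (%s), kappa = %.3f  [%d phase classes, R^2 = %.4f]\n",
    paste(signif(x$model$t_d, 6), collapse = ", "), x$model$kappa,
    nrow(x$bins), x$r_squared))
  invisible(x)
}

#' @rdname estimate_defect
#' @param x an `ltd_fit` object.
#' @param ... unused.
#' @export
tidy.ltd_fit <- function(x, ...) x$bins

#' @rdname estimate_defect
#' @export
glance.ltd_fit <- function(x, ...) {
  tibble(td_1 = x$model$t_d[1], td_2 = x$model$t_d[2], td_3 = x$model$t_d[3],
         kappa = x$model$kappa, residual = x$residual,
         r_squared = x$r_squared, n_bins = nrow(x$bins))
}
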