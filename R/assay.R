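#' Per-droplet fluorescence population
#'
#' Holds the pre-extracted relative fluorescence intensities of a droplet
#' array in scan (stitched-image traversal) order, together with the common
#' droplet volume. Optional ground-truth labels are carried only by
#' synthetic populations.
#'
#' @param intensity Numeric vector of per-droplet intensities (arbitrary
#'   units), finite.
#' @param position Unique, sortable position indices (default scan order
#'   `1..n`).
#' @param volume Droplet volume in uL, > 0.
#' @param truth Optional logical vector of true positive labels (synthetic
#'   data only).
#' @return An object of class `droplet_population`.
#' @export
droplet_population <- function(intensity, position = seq_along(intensity),
                               volume, truth = NULL) {
  if (!is.numeric(intensity) || any(!is.finite(intensity))) {
    stop("`intensity` must be finite numeric", call. = FALSE)
  }
  if (length(position) != length(intensity) || anyDuplicated(position) > 0L) {
    stop("`position` must be unique and match `intensity` in length",
         call. = FALSE)
  }
  .check_num(volume, "volume", positive = TRUE)
  if (!is.null(truth) && (!is.logical(truth) || length(truth) != length(intensity))) {
    stop("`truth` must be a logical vector matching `intensity`", call. = FALSE)
  }
  structure(list(intensity = intensity, position = position,
                 volume = volume, truth = truth),
            class = "droplet_population")
}

#' Global positive/negative intensity threshold
#'
#' Threshold for calling droplets positive: the mean fluorescence intensity
#' of negative-control droplets plus `k_sd` times their sample standard
#' deviation (n-1 denominator). Droplets strictly above the threshold are
#' positive; a droplet exactly at the threshold is negative.
#'
#' @param control_intensity Intensities of negative-control droplets,
#'   length >= 2.
#' @param k_sd SD multiplier, default 3.
#' @return Threshold in intensity units.
#' @examples
#' global_threshold(c(90, 100, 110)) # 130
#' @export
global_threshold <- function(control_intensity, k_sd = 3) {
  if (!is.numeric(control_intensity) || length(control_intensity) < 2L) {
    stop("need at least 2 control intensities to form a threshold",
         call. = FALSE)
  }
  mean(control_intensity) + k_sd * stats::sd(control_intensity)
}

#' Drift-robust local droplet classification
#'
#' Stitched fluorescence scans show periodic baseline fluctuations (focus
#' and illumination vary across image tiles), so a single global threshold
#' misclassifies droplets near drift extremes. This two-pass scheme first
#' assigns provisional labels from a global threshold, then re-tests every
#' droplet against the mean intensity of its `k` nearest provisionally
#' negative neighbours (by position index, i.e. scan order) plus
#' `multiplier` times their SD. Because the provisional negative pool is
#' truncated at the global threshold near drift peaks, the re-test is
#' repeated with the updated labels until they stabilise (at most
#' `max_iter` sweeps); in drift-free populations the first sweep already
#' reproduces the global labels and iteration changes nothing. A zero
#' neighbourhood SD falls back to the global threshold for that droplet;
#' fewer than `k` provisional negatives overall falls back to global
#' thresholding for the whole population, with a warning flag.
#'
#' @param population A [droplet_population()].
#' @param controls Optional negative-control intensities for the global
#'   threshold; when omitted, the population's own intensities are used
#'   (appropriate when negatives dominate).
#' @param k Neighbourhood size, default 10.
#' @param multiplier Neighbourhood SD multiplier, default 5.
#' @param k_sd Global-threshold SD multiplier, default 3.
#' @param max_iter Maximum number of re-test sweeps, default 10.
#' @return An object of class `classification_result`: a list with
#'   `positive` (logical), `p` (positive fraction), `thresholds`
#'   (per-droplet), `global_threshold`, and `fallback`.
#' @export
local_classify <- function(population, controls = NULL, k = 10,
                           multiplier = 5, k_sd = 3, max_iter = 10) {
  stopifnot(inherits(population, "droplet_population"))
  int <- population$intensity
  pos <- population$position
  n <- length(int)
  thr0 <- global_threshold(if (is.null(controls)) int else controls, k_sd)
  negative <- int <= thr0

  if (sum(negative) < k) {
    warning("fewer than k = ", k, " provisional negatives; ",
            "falling back to the global threshold", call. = FALSE)
    positive <- int > thr0
    return(structure(list(positive = positive, p = mean(positive),
                          thresholds = rep(thr0, n),
                          global_threshold = thr0, fallback = TRUE),
                     class = "classification_result"))
  }

  sweep <- function(negative) {
    o <- order(pos[negative])
    neg_pos <- pos[negative][o]
    neg_int <- int[negative][o]
    m <- length(neg_pos)
    thresholds <- numeric(n)
    for (i in seq_len(n)) {
      j <- findInterval(pos[i], neg_pos)
      lo <- max(1L, j - k)
      hi <- min(m, j + k + 1L)
      idx <- lo:hi
      d <- abs(neg_pos[idx] - pos[i])
      if (negative[i]) {
        idx <- idx[d > 0]          # a droplet is not its own neighbour
        d <- d[d > 0]
      }
      sel <- idx[order(d)][seq_len(min(k, length(idx)))]
      mu <- mean(neg_int[sel])
      s <- stats::sd(neg_int[sel])
      thresholds[i] <- if (is.na(s) || s == 0) thr0 else mu + multiplier * s
    }
    thresholds
  }

  thresholds <- rep(thr0, n)
  for (it in seq_len(max_iter)) {
    thresholds <- sweep(negative)
    updated <- int <= thresholds
    if (sum(updated) < k) break   # keep the last usable negative pool
    if (identical(updated, negative)) {
      negative <- updated
      break
    }
    negative <- updated
  }
  positive <- !negative
  structure(list(positive = positive, p = mean(positive),
                 thresholds = thresholds, global_threshold = thr0,
                 fallback = FALSE),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Droplet classification: %d / %d positive (p = %.4f)%s\n",
              sum(x$positive), length(x$positive), x$p,
              if (x$fallback) " [global-threshold fallback]" else ""))
  invisible(x)
}

#' Poisson concentration estimate from the positive-droplet fraction
#'
#' With analytes randomly discretised across droplets, occupancy is Poisson
#' and the positive fraction p gives the concentration
#' `C = -ln(1 - p) / V`. In the dilute limit `C ~ p / V`. A saturated assay
#' (p = 1) carries no finite estimate and is an error. Optionally a Wilson
#' score interval on p is propagated through the same transform (an
#' extension beyond the point estimate; requires the droplet count).
#'
#' @param p Positive fraction in \[0, 1).
#' @param volume Droplet volume in uL, > 0.
#' @param n Optional droplet count, enables the confidence interval.
#' @param conf_level Confidence level for the Wilson interval, default 0.95.
#' @return A list of class `concentration_estimate` with `concentration`
#'   (copies or CFU per uL), `p`, `volume`, and, when `n` is given,
#'   `conf_low`/`conf_high`.
#' @examples
#' poisson_concentration(1 - exp(-1), 1e-3) # 1000 copies/uL
#' @export
poisson_concentration <- function(p, volume, n = NULL, conf_level = 0.95) {
  .check_num(p, "p")
  .check_num(volume, "volume", positive = TRUE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (p == 1) stop("saturated assay: p = 1 admits no finite concentration",
                   call. = FALSE)
  out <- list(concentration = -log(1 - p) / volume, p = p, volume = volume)
  if (!is.null(n)) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    p_lo <- max(0, centre - half)
    p_hi <- min(centre + half, 1 - 1e-12)
    out$conf_low <- -log(1 - p_lo) / volume
    out$conf_high <- -log(1 - p_hi) / volume
  }
  structure(out, class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("Concentration: %.4g per uL (p = %.4g, V = %.4g uL)\n",
              x$concentration, x$p, x$volume))
  if (!is.null(x$conf_low)) {
    cat(sprintf("  Wilson interval: [%.4g, %.4g] per uL\n",
                x$conf_low, x$conf_high))
  }
  invisible(x)
}

#' Dilution linearity of measured against theoretical concentrations
#'
#' Ordinary least squares of log10(measured) on log10(theoretical) over a
#' dilution series. An accurate digital assay gives slope 1, intercept 0
#' and R^2 near 1.
#'
#' @param measured,theoretical Positive concentration vectors of equal
#'   length >= 3.
#' @return A list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
dilution_linearity <- function(measured, theoretical) {
  if (length(measured) != length(theoretical) || length(measured) < 3L) {
    stop("need >= 3 measured/theoretical pairs", call. = FALSE)
  }
  if (any(measured <= 0) || any(theoretical <= 0)) {
    stop("concentrations must be positive for log-log regression",
         call. = FALSE)
  }
  fit <- stats::lm(log10(measured) ~ log10(theoretical))
  cf <- stats::coef(fit)
  y <- log10(measured)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = r2, fit = fit)
}

#' Limit of detection from replicate calls
#'
#' The LOD is the lowest tested concentration that yields a positive call
#' in all replicate experiments.
#'
#' @param calls A named list: names are concentrations (coercible to
#'   numeric), values are logical vectors of replicate positivity.
#' @return A list with `lod` (the concentration, or `NA`) and `reached`.
#' @examples
#' lod(list(`10` = c(FALSE, FALSE, TRUE),
#'          `28.5` = c(TRUE, TRUE, TRUE),
#'          `285` = c(TRUE, TRUE, TRUE)))
#' @export
lod <- function(calls) {
  if (!is.list(calls) || length(calls) == 0L || is.null(names(calls))) {
    stop("`calls` must be a non-empty named list of logical replicate calls",
         call. = FALSE)
  }
  conc <- as.numeric(names(calls))
  if (any(is.na(conc))) stop("names of `calls` must be concentrations", call. = FALSE)
  all_pos <- vapply(calls, function(x) all(as.logical(x)), logical(1))
  o <- order(conc)
  hit <- which(all_pos[o])
  if (length(hit) == 0L) {
    return(list(lod = NA_real_, reached = FALSE))
  }
  list(lod = conc[o][hit[1L]], reached = TRUE)
}

#' Minimum inhibitory concentration from a droplet survival curve
#'
#' The MIC is read off the droplet-level survival curve as the lowest
#' antibiotic concentration that suppresses survival to at most the cutoff
#' (10 percent by convention).
#'
#' @param curve A data frame with columns `concentration` (strictly
#'   increasing, e.g. ug/mL) and `survival_pct` (in \[0, 100\]).
#' @param cutoff Survival cutoff in percent, default 10.
#' @return A list with `mic` (the concentration, or `NA`) and `reached`.
#' @examples
#' mic(data.frame(concentration = c(0, 0.5, 1, 2),
#'                survival_pct = c(100, 60, 8, 1)))
#' @export
mic <- function(curve, cutoff = 10) {
  if (!is.data.frame(curve) || nrow(curve) == 0L ||
      !all(c("concentration", "survival_pct") %in% names(curve))) {
    stop("`curve` must be a non-empty data frame with columns ",
         "`concentration` and `survival_pct`", call. = FALSE)
  }
  if (is.unsorted(curve$concentration, strictly = TRUE)) {
    stop("`concentration` must be strictly increasing", call. = FALSE)
  }
  if (any(curve$survival_pct < 0 | curve$survival_pct > 100)) {
    stop("`survival_pct` must lie in [0, 100]", call. = FALSE)
  }
  hit <- which(curve$survival_pct <= cutoff)
  if (length(hit) == 0L) {
    return(list(mic = NA_real_, reached = FALSE))
  }
  list(mic = curve$concentration[hit[1L]], reached = TRUE)
}
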