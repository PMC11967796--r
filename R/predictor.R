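#' Resistance factor of the connection tube
#'
#' When a droplet ("ballon") grows at a step nozzle it stays connected to
#' the microchannel by a transient liquid neck, the connection tube. The
#' lumped resistance factor links the Laplace pressure difference between
#' channel meniscus and ballon to the inlet flow rate:
#' `R_f = 2 gamma (1/w + 1/h - 2/D) / V_in`.
#' R_f vanishes at `D = 2wh/(w+h)` (the hydraulic diameter, the smallest
#' ballon the bracket admits) and increases strictly with D.
#'
#' @param condition An [emul_condition()] with positive inlet velocity.
#' @param diameter Droplet diameter D (m); may be a vector.
#' @return Resistance factor(s) in Pa s m^-1.
#' @examples
#' ch <- channel_geometry(20e-6, 20e-6, 5e-3)
#' fl <- fluid_system(1000, 1e-3, 5e-3, deg_to_rad(120))
#' ro <- rotor_config(rpm_to_rad_s(5000), 18e-3, 6e-3)
#' resistance_factor(emul_condition(ch, fl, ro), 150e-6)
#' @export
resistance_factor <- function(condition, diameter) {
  stopifnot(inherits(condition, "emul_condition"))
  if (condition$v_in <= 0 || condition$no_flow) {
    stop("no flow: resistance factor undefined at V_in = 0", call. = FALSE)
  }
  stopifnot(all(diameter > 0))
  .rf(condition$fluids$surface_tension, condition$channel$width,
      condition$channel$height, diameter, condition$v_in)
}

.rf <- function(gamma, w, h, D, v_in) {
  2 * gamma * (1 / w + 1 / h - 2 / D) / v_in
}

#' Fit the per-acceleration exponential law R_f = alpha exp(-beta D)
#'
#' At a given centrifugal acceleration, resistance factors are exponentially
#' related to droplet diameters irrespective of microchannel dimensions.
#' The law is fitted by ordinary least squares in log space
#' (`ln R_f = ln alpha - beta D`), which stabilises the variance over the
#' orders of magnitude R_f spans and has a deterministic closed-form
#' solution.
#'
#' @param diameter Droplet diameters (m), length >= 3.
#' @param rf Matching resistance factors (Pa s m^-1), all > 0.
#' @param acceleration Centrifugal acceleration the group belongs to
#'   (m s^-2); kept as metadata.
#' @return An object of class `exp_law`: a list with `acceleration`,
#'   `alpha` (Pa s m^-1), `beta` (m^-1), `r_squared` and `n`.
#' @export
fit_exp_law <- function(diameter, rf, acceleration = NA_real_) {
  if (length(diameter) != length(rf)) {
    stop("`diameter` and `rf` must have equal length", call. = FALSE)
  }
  if (length(rf) < 3L) {
    stop("exponential-law fit needs at least 3 observations, got ",
         length(rf), call. = FALSE)
  }
  if (any(!is.finite(rf)) || any(rf <= 0)) {
    stop("all resistance factors must be positive and finite; ",
         sum(!is.finite(rf) | rf <= 0), " offending value(s)", call. = FALSE)
  }
  fit <- stats::lm(log(rf) ~ diameter)
  cf <- stats::coef(fit)
  alpha <- exp(unname(cf[1L]))
  beta <- -unname(cf[2L])
  if (beta <= 0) {
    warning("fitted beta is non-positive; data are inconsistent with a ",
            "decaying exponential law", call. = FALSE)
  }
  # R^2 computed directly; summary.lm() warns on noise-free (exact) fits
  y <- log(rf)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(acceleration = acceleration, alpha = alpha, beta = beta,
                 r_squared = r2, n = length(rf)),
            class = "exp_law")
}

# Greedy 1-D clustering of accelerations: values within `rtol` (relative) of
# a cluster centre share a group. Centres are running means.
.cluster_accelerations <- function(a, rtol) {
  o <- order(a)
  groups <- integer(length(a))
  centres <- numeric(0)
  counts <- integer(0)
  for (i in o) {
    hit <- which(abs(a[i] - centres) <= rtol * centres)
    if (length(hit) >= 1L) {
      g <- hit[1L]
      centres[g] <- (centres[g] * counts[g] + a[i]) / (counts[g] + 1L)
      counts[g] <- counts[g] + 1L
    } else {
      centres <- c(centres, a[i])
      counts <- c(counts, 1L)
      g <- length(centres)
    }
    groups[i] <- g
  }
  list(group = groups, centre = centres)
}

#' Fit a droplet-size predictive model from an observation table
#'
#' Groups observations by centrifugal acceleration (relative tolerance
#' `group_rtol`, absorbing floating-point jitter in rotor settings), drops
#' conditions outside the periodic dripping regime, converts each observed
#' mean diameter to a resistance factor via [resistance_factor()], and fits
#' one exponential law per acceleration group with [fit_exp_law()]. Groups
#' with fewer than three eligible observations are skipped with a message.
#'
#' @param observations A data frame in the tabular interchange convention:
#'   columns `w_um, h_um, l_mm, rho_kg_m3, mu_mPa_s, gamma_mN_m, theta_deg,
#'   omega_rpm, R1_mm, R2_mm, D_um` (plus optional `cv_pct`, `n_droplets`).
#' @param group_rtol Relative tolerance for acceleration grouping
#'   (default 0.01).
#' @param we_threshold Weber regime boundary, see [classify_regime()].
#' @return An object of class `droplet_model`: a list with `laws` (a data
#'   frame with columns `acceleration, alpha, beta, r_squared, n`) and
#'   `group_rtol`.
#' @seealso [predict_diameter()], [evaluate_model()], [write_droplet_model()]
#' @export
fit_droplet_model <- function(observations, group_rtol = 0.01, we_threshold = 1) {
  conds <- conditions_from_table(observations, we_threshold = we_threshold)
  a <- vapply(conds, `[[`, numeric(1), "acceleration")
  eligible <- vapply(conds, function(co) {
    identical(co$regime, "periodic_dripping") && co$v_in > 0
  }, logical(1))
  if (!any(eligible)) {
    stop("no observations in the periodic dripping regime; nothing to fit",
         call. = FALSE)
  }
  cl <- .cluster_accelerations(a, group_rtol)
  laws <- list()
  for (g in sort(unique(cl$group))) {
    idx <- which(cl$group == g & eligible)
    if (length(idx) < 3L) {
      message("skipping acceleration group at ", signif(cl$centre[g], 5),
              " m/s^2: only ", length(idx), " eligible observation(s)")
      next
    }
    D <- observations$D_um[idx] * .UM
    rf <- vapply(seq_along(idx), function(k) {
      resistance_factor(conds[[idx[k]]], D[k])
    }, numeric(1))
    law <- fit_exp_law(D, rf, acceleration = cl$centre[g])
    laws[[length(laws) + 1L]] <- law
  }
  if (length(laws) == 0L) {
    stop("no acceleration group had the 3 observations needed for a fit",
         call. = FALSE)
  }
  structure(list(
    laws = data.frame(
      acceleration = vapply(laws, `[[`, numeric(1), "acceleration"),
      alpha = vapply(laws, `[[`, numeric(1), "alpha"),
      beta = vapply(laws, `[[`, numeric(1), "beta"),
      r_squared = vapply(laws, `[[`, numeric(1), "r_squared"),
      n = vapply(laws, `[[`, numeric(1), "n")
    ),
    group_rtol = group_rtol
  ), class = "droplet_model")
}

# Resolve (alpha, beta) for an acceleration: exact group match within rtol,
# else optional piecewise-linear interpolation of ln(alpha) and beta in a.
.match_law <- function(model, a, interpolate = FALSE) {
  laws <- model$laws
  rel <- abs(laws$acceleration - a) / laws$acceleration
  hit <- which(rel <= model$group_rtol)
  if (length(hit) >= 1L) {
    i <- hit[which.min(rel[hit])]
    return(list(alpha = laws$alpha[i], beta = laws$beta[i], interpolated = FALSE))
  }
  if (!interpolate) {
    stop("untrained acceleration: no fitted law within ",
         100 * model$group_rtol, "% of a = ", signif(a, 6),
         " m/s^2 (enable `interpolate` or refit)", call. = FALSE)
  }
  if (nrow(laws) < 2L || a < min(laws$acceleration) || a > max(laws$acceleration)) {
    stop("acceleration a = ", signif(a, 6),
         " m/s^2 outside the interpolation range of the fitted laws",
         call. = FALSE)
  }
  o <- order(laws$acceleration)
  lnalpha <- stats::approx(laws$acceleration[o], log(laws$alpha[o]), xout = a)$y
  beta <- stats::approx(laws$acceleration[o], laws$beta[o], xout = a)$y
  list(alpha = exp(lnalpha), beta = beta, interpolated = TRUE)
}

# Bracketed solve of 2 gamma (1/w + 1/h - 2/D)/V_in = alpha exp(-beta D) on
# D in (D_h (1+1e-6), d_max]. The left side rises strictly from 0, the right
# side decays and stays positive, so at most one root exists; the bracket is
# certified before solving and the root is Newton-polished to a relative
# residual below 1e-10.
.solve_diameter <- function(gamma, w, h, v_in, alpha, beta, d_max = 1e-3) {
  stopifnot(v_in > 0, alpha > 0, beta > 0)
  dh <- 2 * w * h / (w + h)
  lo <- dh * (1 + 1e-6)
  g <- function(D) .rf(gamma, w, h, D, v_in) - alpha * exp(-beta * D)
  if (g(lo) > 0) {
    stop("outside model range: no root above the bracket lower bound",
         call. = FALSE)
  }
  if (g(d_max) < 0) {
    stop("outside model range: no root below d_max = ", format(d_max),
         " m", call. = FALSE)
  }
  D <- stats::uniroot(g, c(lo, d_max), tol = 1e-12)$root
  # Newton polish to machine-level relative residual
  for (k in 1:8) {
    lhs <- .rf(gamma, w, h, D, v_in)
    rhs <- alpha * exp(-beta * D)
    res <- lhs - rhs
    if (abs(res) <= 1e-10 * rhs) break
    dg <- 4 * gamma / (v_in * D^2) + beta * rhs
    D <- D - res / dg
  }
  D
}

#' Predict the droplet diameter for a condition
#'
#' Solves the diameter equation
#' `2 gamma (1/w + 1/h - 2/D) / V_in = alpha exp(-beta D)`
#' for the unique root above the hydraulic diameter, using the exponential
#' law fitted at the condition's centrifugal acceleration. The left side is
#' strictly increasing from zero and the right side strictly decreasing and
#' positive, so the bracketed root is unique; it is located by a certified
#' bracketed solver and polished to a relative residual below 1e-10.
#'
#' @param condition An [emul_condition()] in the periodic dripping regime
#'   with positive inlet velocity.
#' @param model A `droplet_model` from [fit_droplet_model()] (or read back
#'   with [read_droplet_model()]).
#' @param interpolate If `TRUE`, conditions at accelerations between fitted
#'   laws use piecewise-linear interpolation of `ln alpha` and `beta`;
#'   flagged in the `interpolated` attribute. The default is a hard error,
#'   since the laws are fitted per acceleration.
#' @param d_max Upper bracket for the root (m), default 1 mm.
#' @return Predicted diameter (m) with attribute `interpolated`.
#' @export
predict_diameter <- function(condition, model, interpolate = FALSE, d_max = 1e-3) {
  stopifnot(inherits(condition, "emul_condition"), inherits(model, "droplet_model"))
  if (condition$no_flow || condition$v_in <= 0) {
    stop("no flow: cannot predict a diameter at V_in = 0", call. = FALSE)
  }
  if (!identical(condition$regime, "periodic_dripping")) {
    stop("condition is in the ", condition$regime,
         " regime; the diameter law only covers periodic dripping",
         call. = FALSE)
  }
  law <- .match_law(model, condition$acceleration, interpolate)
  D <- .solve_diameter(condition$fluids$surface_tension,
                       condition$channel$width, condition$channel$height,
                       condition$v_in, law$alpha, law$beta, d_max)
  structure(D, interpolated = law$interpolated)
}

#' Droplet generation frequency
#'
#' `f = 6 w h V_in / (pi D^3)`: the volumetric rate through one channel
#' divided by the droplet volume, so `f * pi D^3 / 6 = w h V_in` exactly.
#'
#' @param condition An [emul_condition()].
#' @param diameter Droplet diameter D (m), > 0.
#' @return Frequency in s^-1 (per channel).
#' @export
predict_frequency <- function(condition, diameter) {
  stopifnot(inherits(condition, "emul_condition"), all(diameter > 0))
  if (condition$v_in <= 0) stop("no flow: frequency undefined", call. = FALSE)
  6 * condition$channel$width * condition$channel$height * condition$v_in /
    (pi * diameter^3)
}

#' Train/validation evaluation of the predictive model
#'
#' Splits an observation table into training and validation subsets by a
#' seeded pseudo-random draw stratified by acceleration group (default 2/3
#' training), fits the exponential laws on the training subset, predicts the
#' validation diameters and reports the mean absolute relative error
#' `mean(100 |D_pred - D_obs| / D_obs)`.
#'
#' @inheritParams fit_droplet_model
#' @param split Training fraction in (0, 1), default 2/3.
#' @param seed Integer seed for the split (reproducibility).
#' @return An object of class `model_evaluation`: a list with `error_pct`,
#'   `n_train`, `n_validation`, `details` (per-validation-point data frame)
#'   and the fitted `model`.
#' @export
evaluate_model <- function(observations, split = 2 / 3, seed = NULL,
                           group_rtol = 0.01, we_threshold = 1) {
  stopifnot(split > 0, split < 1)
  conds <- conditions_from_table(observations, we_threshold = we_threshold)
  a <- vapply(conds, `[[`, numeric(1), "acceleration")
  eligible <- vapply(conds, function(co) {
    identical(co$regime, "periodic_dripping") && co$v_in > 0
  }, logical(1))
  cl <- .cluster_accelerations(a, group_rtol)
  groups <- sort(unique(cl$group[eligible]))
  if (length(groups) < 2L) {
    stop("dataset must span at least 2 acceleration groups, found ",
         length(groups), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  train_idx <- integer(0)
  deficient <- character(0)
  for (g in groups) {
    idx <- which(cl$group == g & eligible)
    n_tr <- round(split * length(idx))
    if (n_tr < 3L) {
      deficient <- c(deficient, sprintf("a = %s m/s^2 (%d points, %d in training)",
                                        signif(cl$centre[g], 5), length(idx), n_tr))
      next
    }
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  if (length(deficient) > 0L) {
    stop("training split leaves fewer than 3 points in: ",
         paste(deficient, collapse = "; "), call. = FALSE)
  }
  val_idx <- setdiff(which(eligible), train_idx)

  laws <- list()
  for (g in groups) {
    idx <- intersect(which(cl$group == g), train_idx)
    D <- observations$D_um[idx] * .UM
    rf <- vapply(seq_along(idx), function(k) {
      resistance_factor(conds[[idx[k]]], D[k])
    }, numeric(1))
    laws[[as.character(g)]] <- fit_exp_law(D, rf, acceleration = cl$centre[g])
  }
  model <- structure(list(
    laws = data.frame(
      acceleration = vapply(laws, `[[`, numeric(1), "acceleration"),
      alpha = vapply(laws, `[[`, numeric(1), "alpha"),
      beta = vapply(laws, `[[`, numeric(1), "beta"),
      r_squared = vapply(laws, `[[`, numeric(1), "r_squared"),
      n = vapply(laws, `[[`, numeric(1), "n"),
      row.names = NULL
    ),
    group_rtol = group_rtol
  ), class = "droplet_model")

  d_obs <- observations$D_um[val_idx] * .UM
  d_pred <- vapply(seq_along(val_idx), function(k) {
    law <- laws[[as.character(cl$group[val_idx[k]])]]
    .solve_diameter(conds[[val_idx[k]]]$fluids$surface_tension,
                    conds[[val_idx[k]]]$channel$width,
                    conds[[val_idx[k]]]$channel$height,
                    conds[[val_idx[k]]]$v_in, law$alpha, law$beta)
  }, numeric(1))
  rel_err <- 100 * abs(d_pred - d_obs) / d_obs

  structure(list(
    error_pct = mean(rel_err),
    n_train = length(train_idx),
    n_validation = length(val_idx),
    details = data.frame(
      acceleration = a[val_idx],
      d_obs_um = d_obs / .UM,
      d_pred_um = d_pred / .UM,
      rel_err_pct = rel_err
    ),
    model = model
  ), class = "model_evaluation")
}

#' @export
print.droplet_model <- function(x, ...) {
  cat("Droplet-size predictive model:", nrow(x$laws),
      "per-acceleration exponential law(s)\n")
  print(x$laws, row.names = FALSE)
  invisible(x)
}

#' @export
print.exp_law <- function(x, ...) {
  cat(sprintf(
    "Exponential law at a = %s m/s^2: alpha = %.4g Pa s/m, beta = %.4g 1/m (R^2 = %.4f, n = %d)\n",
    signif(x$acceleration, 6), x$alpha, x$beta, x$r_squared, x$n))
  invisible(x)
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "Model evaluation: %d training / %d validation points, mean absolute relative error %.2f%%\n",
    x$n_train, x$n_validation, x$error_pct))
  invisible(x)
}
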