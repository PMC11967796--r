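# Tabular interchange: conditions and observations travel as delimited text
# with unit-tagged column names; models as JSON; traces as CSV.

.COND_COLS <- c("w_um", "h_um", "l_mm", "rho_kg_m3", "mu_mPa_s",
                "gamma_mN_m", "theta_deg", "omega_rpm", "R1_mm", "R2_mm")

#' Read emulsification conditions or observations from delimited text
#'
#' Conditions use header columns `w_um, h_um, l_mm, rho_kg_m3, mu_mPa_s,
#' gamma_mN_m, theta_deg, omega_rpm, R1_mm, R2_mm`; observation tables add
#' `D_um` (and optionally `cv_pct`, `n_droplets`). A `.json` file holding an
#' array of records with the same fields is accepted equivalently.
#'
#' @param path Path to a CSV (or JSON) file.
#' @return A data frame.
#' @export
read_conditions <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  missing <- setdiff(.COND_COLS, names(df))
  if (length(missing) > 0L) {
    stop("condition table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_conditions
#' @export
read_observations <- function(path) {
  df <- read_conditions(path)
  if (!"D_um" %in% names(df)) {
    stop("observation table lacks the `D_um` column", call. = FALSE)
  }
  df
}

#' Build emulsification conditions from a table row or table
#'
#' Converts the unit-tagged tabular representation (um, mm, rpm, degrees,
#' mN/m, mPa s) into SI [emul_condition()] objects.
#'
#' @param table A data frame with the condition columns of
#'   [read_conditions()].
#' @param we_threshold Weber regime boundary.
#' @return A list of [emul_condition()] objects (one per row).
#' @export
conditions_from_table <- function(table, we_threshold = 1) {
  missing <- setdiff(.COND_COLS, names(table))
  if (length(missing) > 0L) {
    stop("condition table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    emul_condition(
      channel_geometry(row$w_um * .UM, row$h_um * .UM, row$l_mm * .MM),
      fluid_system(row$rho_kg_m3, row$mu_mPa_s * .MPA_S,
                   row$gamma_mN_m * .MN_M, deg_to_rad(row$theta_deg)),
      rotor_config(rpm_to_rad_s(row$omega_rpm), row$R1_mm * .MM,
                   row$R2_mm * .MM),
      we_threshold
    )
  })
}

#' Serialize a fitted droplet model to JSON and back
#'
#' The model is stored as a JSON array of per-acceleration laws
#' `{a_m_s2, alpha, beta, r2, n}` plus the grouping tolerance.
#'
#' @param model A `droplet_model` from [fit_droplet_model()].
#' @param path Destination / source path.
#' @return `write_droplet_model()` returns `path` invisibly;
#'   `read_droplet_model()` returns a `droplet_model`.
#' @export
write_droplet_model <- function(model, path) {
  stopifnot(inherits(model, "droplet_model"))
  jsonlite::write_json(
    list(group_rtol = model$group_rtol,
         laws = data.frame(a_m_s2 = model$laws$acceleration,
                           alpha = model$laws$alpha,
                           beta = model$laws$beta,
                           r2 = model$laws$r_squared,
                           n = model$laws$n)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_droplet_model
#' @export
read_droplet_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  laws <- as.data.frame(obj$laws)
  structure(list(
    laws = data.frame(acceleration = laws$a_m_s2, alpha = laws$alpha,
                      beta = laws$beta, r_squared = laws$r2, n = laws$n),
    group_rtol = obj$group_rtol
  ), class = "droplet_model")
}

#' Export a depletion trace as CSV
#'
#' Columns: `t_s, V_uL, R1_mm, R2_mm, Vin_mm_s`.
#'
#' @param trace A `depletion_trace` from [simulate_depletion()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_depletion_trace <- function(trace, path) {
  stopifnot(inherits(trace, "depletion_trace"))
  tr <- trace$trace
  utils::write.csv(
    data.frame(t_s = tr$time, V_uL = tr$volume / .UL, R1_mm = tr$r1 / .MM,
               R2_mm = tr$r2 / .MM, Vin_mm_s = tr$v_in / .MM),
    path, row.names = FALSE)
  invisible(path)
}
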