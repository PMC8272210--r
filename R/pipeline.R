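# Orchestration: simulate (or load) -> two-component fits -> phase
# assignment -> correlation times -> per-phase Arrhenius activation
# energies, plus the tabular I/O and the fatty-acid summary utility.

.component_table_cols <- c("starch", "concentration_g_per_g", "fat",
                           "temperature_c", "t11_s", "t12_s", "t21_s",
                           "t22_s", "fraction_oil")

#' Read a per-temperature relaxation component table
#'
#' The long-format exchange table for pre-fitted components: one row per
#' (condition, temperature) with the two T1 components (`t11_s` oil,
#' `t12_s` water), the two T2 components (`t21_s` oil, `t22_s` water) and
#' the oil proton fraction. Schema is validated strictly: missing columns,
#' non-numeric cells and duplicate (condition, temperature) keys are
#' errors naming the offender.
#'
#' @param path CSV file path.
#' @return A data frame with the columns above.
#' @seealso [write_component_table()]
#' @export
read_component_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.component_table_cols, names(d))
  if (length(miss))
    stop("component table is missing column(s): ",
         paste(miss, collapse = ", "))
  num_cols <- setdiff(.component_table_cols, c("starch", "fat"))
  for (cc in num_cols) {
    v <- d[[cc]]
    if (!is.numeric(v))
      stop("column '", cc, "' contains non-numeric values")
  }
  key <- interaction(d$starch, d$concentration_g_per_g, d$fat,
                     d$temperature_c, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (condition, temperature) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- with(d, t11_s >= t12_s | t21_s >= t22_s)
  if (any(bad))
    stop("oil components must be shorter than water components; violated ",
         "at temperature(s) ", paste(d$temperature_c[bad], collapse = ", "))
  d[, .component_table_cols]
}

#' Write a per-temperature relaxation component table
#'
#' Inverse of [read_component_table()]; `write` then `read` is the
#' identity on the data model.
#'
#' @param table A data frame with the component-table schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(table, path) {
  miss <- setdiff(.component_table_cols, names(table))
  if (length(miss))
    stop("component table is missing column(s): ",
         paste(miss, collapse = ", "))
  utils::write.csv(table[, .component_table_cols], path, row.names = FALSE)
  invisible(path)
}

# tau_c per phase from a pair of (T1, T2) values, by the configured mode
.extract_tau <- function(t1, t2, ctx, mode, branch) {
  if (mode == "ratio") {
    tau_c_from_ratio(t1 / t2, ctx)  # R2/R1 = T1/T2
  } else {
    tau_c_from_r1(1 / t1, ctx, branch = branch)
  }
}

#' Run the full emulsion relaxometry pipeline
#'
#' For each temperature: two-component inversion-recovery and CPMG fits,
#' short/long phase assignment, correlation-time extraction per phase, and
#' finally a per-phase Arrhenius fit — yielding the activation-energy
#' table. Any stage failure is rethrown with the condition and temperature
#' attached.
#'
#' The default correlation-time mode is `"ratio"` (invert the K-free R2/R1
#' expression), which requires no internuclear distance. Mode `"r1"`
#' inverts the absolute R1 rate instead and needs `r0` (default 1.8e-10 m,
#' a typical intramolecular proton pair) and a `branch` (`"fast"` or
#' `"slow"`).
#'
#' @param config A list:
#'   \describe{
#'     \item{dataset}{an `emulsion_dataset` from [generate_dataset()], or}
#'     \item{sim_spec}{an [emulsion_sim_spec()] to generate one, or}
#'     \item{component_table}{a pre-fitted component table (data frame or
#'       CSV path, schema of [read_component_table()]).}
#'     \item{mode}{`"ratio"` (default) or `"r1"`.}
#'     \item{branch}{for mode `"r1"`: `"fast"` or `"slow"`.}
#'     \item{r0}{for mode `"r1"`: internuclear distance in m.}
#'     \item{larmor_frequency_hz}{frequency for component-table input
#'       (default 15e6; dataset input carries its own).}
#'   }
#' @return A list of class `emulsion_pipeline_result`:
#'   `activation_table` (see [activation_energy_table()]), `arrhenius`
#'   (per-phase fits), `tau_c` (per temperature and phase), `diagnostics`
#'   (per-temperature fit quality, clamped ratios, convergence flags).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  mode <- config$mode %||% "ratio"
  if (!mode %in% c("ratio", "r1"))
    stop("unknown correlation-time mode '", mode,
         "'; use \"ratio\" or \"r1\"")
  branch <- config$branch %||% "fast"
  if (mode == "ratio") {
    ctx <- bpp_context(config$larmor_frequency_hz %||% 15e6)
  } else {
    ctx <- bpp_context(config$larmor_frequency_hz %||% 15e6,
                       r0 = config$r0 %||% 1.8e-10)
  }

  if (!is.null(config$component_table)) {
    tab <- config$component_table
    if (is.character(tab)) tab <- read_component_table(tab)
    return(.pipeline_from_components(tab, ctx, mode, branch))
  }

  dataset <- config$dataset
  if (is.null(dataset)) {
    if (is.null(config$sim_spec))
      stop("config must provide one of: dataset, sim_spec, component_table")
    dataset <- generate_dataset(config$sim_spec)
  }
  stopifnot(inherits(dataset, "emulsion_dataset"))
  if (length(dataset$traces) == 0)
    stop("empty temperature series for condition '",
         dataset$spec$metadata$starch, "'")
  ctx <- bpp_context(dataset$spec$larmor_frequency_hz,
                     r0 = if (mode == "r1") config$r0 %||% 1.8e-10)

  md <- dataset$spec$metadata
  tau <- list(); diag <- list()
  for (key in names(dataset$traces)) {
    entry <- dataset$traces[[key]]
    tc <- entry$temperature_c
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) stop(
        sprintf("[%s, %.1f C, %s] %s", md$starch, tc, what,
                conditionMessage(e)), call. = FALSE))
    }
    fit1 <- step("T1 fit", fit_inversion_recovery(entry$ir, 2))
    fit2 <- step("T2 fit", fit_cpmg(entry$cpmg, 2))
    ph <- step("phase assignment", assign_phases(fit1, fit2))
    tk <- celsius_to_kelvin(tc)
    for (phase in c("oil", "water")) {
      comp <- ph[[phase]]
      t1 <- comp$time_constant_s[comp$which == "T1"]
      t2 <- comp$time_constant_s[comp$which == "T2"]
      est <- step(paste(phase, "tau_c"),
                  .extract_tau(t1, t2, ctx, mode, branch))
      est$temperature_k <- tk
      tau[[paste(key, phase)]] <- data.frame(
        temperature_c = tc, temperature_k = tk, phase = phase,
        t1_s = t1, t2_s = t2, tau_c_s = est$tau_c,
        ratio_clamped = est$clamped, stringsAsFactors = FALSE)
    }
    diag[[key]] <- data.frame(
      temperature_c = tc,
      ir_converged = fit1$converged, cpmg_converged = fit2$converged,
      ir_residual_rms = fit1$residual_rms,
      cpmg_residual_rms = fit2$residual_rms, stringsAsFactors = FALSE)
  }
  tau <- do.call(rbind, tau); rownames(tau) <- NULL
  diag <- do.call(rbind, diag); rownames(diag) <- NULL
  .finish_pipeline(tau, diag, md)
}

.pipeline_from_components <- function(tab, ctx, mode, branch) {
  if (nrow(tab) == 0) stop("empty component table")
  keys <- unique(tab[, c("starch", "concentration_g_per_g", "fat")])
  results <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab$starch == keys$starch[i] &
      tab$concentration_g_per_g == keys$concentration_g_per_g[i] &
      tab$fat == keys$fat[i]
    sub <- tab[sel, ]
    if (nrow(sub) == 0)
      stop("empty temperature series for condition '", keys$starch[i], "'")
    tau <- do.call(rbind, lapply(seq_len(nrow(sub)), function(j) {
      tk <- celsius_to_kelvin(sub$temperature_c[j])
      rbind(
        data.frame(temperature_c = sub$temperature_c[j], temperature_k = tk,
                   phase = "oil", t1_s = sub$t11_s[j], t2_s = sub$t21_s[j],
                   tau_c_s = NA_real_, ratio_clamped = NA),
        data.frame(temperature_c = sub$temperature_c[j], temperature_k = tk,
                   phase = "water", t1_s = sub$t12_s[j], t2_s = sub$t22_s[j],
                   tau_c_s = NA_real_, ratio_clamped = NA)
      )
    }))
    for (j in seq_len(nrow(tau))) {
      est <- tryCatch(
        .extract_tau(tau$t1_s[j], tau$t2_s[j], ctx, mode, branch),
        error = function(e) stop(sprintf(
          "[%s, %.1f C, %s tau_c] %s", keys$starch[i], tau$temperature_c[j],
          tau$phase[j], conditionMessage(e)), call. = FALSE))
      tau$tau_c_s[j] <- est$tau_c
      tau$ratio_clamped[j] <- est$clamped
    }
    md <- list(starch = keys$starch[i],
               concentration_g_per_g = keys$concentration_g_per_g[i],
               fat = keys$fat[i])
    .finish_pipeline(tau, diag = NULL, md)
  })
  if (length(results) == 1) return(results[[1]])
  structure(
    list(
      activation_table = do.call(rbind, lapply(results,
                                               `[[`, "activation_table")),
      arrhenius = do.call(c, lapply(results, `[[`, "arrhenius")),
      tau_c = do.call(rbind, lapply(results, `[[`, "tau_c")),
      diagnostics = NULL
    ),
    class = "emulsion_pipeline_result"
  )
}

.finish_pipeline <- function(tau, diag, md) {
  fits <- lapply(c("oil", "water"), function(phase) {
    sub <- tau[tau$phase == phase, ]
    fit_arrhenius(sub$tau_c_s, sub$temperature_k, phase = phase)
  })
  meta <- data.frame(starch = md$starch %||% NA_character_,
                     concentration_g_per_g =
                       md$concentration_g_per_g %||% NA_real_,
                     fat = md$fat %||% NA_character_,
                     stringsAsFactors = FALSE)[rep(1, 2), ]
  at <- activation_energy_table(fits, meta)
  names(fits) <- c("oil", "water")
  structure(
    list(activation_table = at, arrhenius = fits, tau_c = tau,
         diagnostics = diag),
    class = "emulsion_pipeline_result"
  )
}

#' @export
print.emulsion_pipeline_result <- function(x, ...) {
  cat("emulsion pipeline result\n")
  writeLines(paste0("  ", format_activation_table(x$activation_table)))
  if (!is.null(x$tau_c) && any(x$tau_c$ratio_clamped, na.rm = TRUE))
    cat(sprintf("  note: %d ratio(s) clamped to the physical minimum\n",
                sum(x$tau_c$ratio_clamped, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged fatty-acid profiles
#'
#' Gas-chromatography fatty-acid compositions (% of total) of the beef and
#' pork fats used as emulsion oil phases, shipped as a package fixture.
#' Totals fall a little short of 100% (pork ~97.1%) because minor acids
#' are not resolved; totals outside `[95, 101]` trigger a warning.
#'
#' @param fat `"beef"` or `"pork"`.
#' @return An object of class `fatty_acid_profile`: data frame with
#'   columns `code` (e.g. `"C16:0"`), `name`, `percent`, `sd`, plus
#'   attribute `fat`.
#' @export
fatty_acid_profile <- function(fat = c("beef", "pork")) {
  fat <- match.arg(fat)
  path <- system.file("extdata", "fatty_acid_profiles.csv",
                      package = "lfnmr", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$fat == fat, c("code", "name", "percent", "sd")]
  rownames(d) <- NULL
  total <- sum(d$percent)
  if (total < 95 || total > 101)
    warning(sprintf("%s profile total %.2f%% lies outside [95, 101]",
                    fat, total))
  structure(d, class = c("fatty_acid_profile", "data.frame"), fat = fat)
}

#' Sum fatty-acid groups from a profile
#'
#' Sums the percentage composition over named groups of acid codes (e.g.
#' the saturated pair C16:0 + C18:0), rounding half-up to one decimal for
#' display. Group members missing from the profile contribute 0 with a
#' warning; an empty group is an error.
#'
#' @param profile A [fatty_acid_profile()].
#' @param groups Named list of character vectors of acid codes.
#' @return Named numeric vector of group sums (%), rounded half-up to one
#'   decimal; the unrounded sums are attached as attribute `"exact"`.
#' @examples
#' \dontrun{
#' summarize_fatty_acids(fatty_acid_profile("beef"),
#'                       list(saturated = c("C16:0", "C18:0")))
#' }
#' @export
summarize_fatty_acids <- function(profile, groups) {
  stopifnot(inherits(profile, "fatty_acid_profile"), is.list(groups),
            length(groups) >= 1, !is.null(names(groups)))
  exact <- vapply(names(groups), function(g) {
    codes <- groups[[g]]
    if (length(codes) == 0)
      stop("fatty-acid group '", g, "' is empty")
    hit <- codes %in% profile$code
    if (!all(hit))
      warning("group '", g, "': code(s) not in profile, treated as 0: ",
              paste(codes[!hit], collapse = ", "), call. = FALSE)
    sum(profile$percent[profile$code %in% codes])
  }, numeric(1))
  out <- round_half_up(exact, 1)
  attr(out, "exact") <- exact
  out
}

#' Reference activation-energy values (not recomputable)
#'
#' The published per-condition activation energies for starch-stabilized
#' emulsions (two starches x three concentrations x two fats x two
#' phases), shipped as reference data for comparison and schema examples.
#' These derive from undeposited raw measurements and cannot be recomputed
#' here; they are regression/reference values only.
#'
#' @return A data frame with columns `starch`, `concentration_g_per_g`,
#'   `fat`, `phase`, `delta_ea_kj_mol`, `se_kj_mol`.
#' @export
reference_activation_energies <- function() {
  path <- system.file("extdata", "reference_activation_energies.csv",
                      package = "lfnmr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
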