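#' Read and validate an RDS survey flat file
#'
#' Reads a survey CSV into an [rds_sample()], applying the two-step
#' behavioural eligibility rule when the screening columns are present:
#' a respondent is eligible if they report sex with another man in the
#' last year (`sex_with_man = 1`), or report `sex_with_man = 0` but do
#' not prefer sex with women only (`prefer_women_only = 0`). Ineligible
#' rows are counted and excluded.
#'
#' Two link formats are accepted: an explicit `recruiter_id` column, or
#' coupon columns (`own_coupon` plus `coupon_1`, `coupon_2`, ...), in
#' which case recruiter links are reconstructed by matching each
#' respondent's `own_coupon` against the coupons issued by recruiters.
#' A coupon issued by more than one respondent is an error.
#'
#' Row-level validation (degree < 1, age < 18, unknown recruiter)
#' drops the offending rows with a warning naming the line numbers; the
#' file is rejected when more than 5% of rows are bad.
#'
#' @param path CSV file path (or a data frame).
#' @param traits optional trait column names passed to [rds_sample()].
#' @return an [rds_sample()] with attributes `n_ineligible` and
#'   `n_dropped`.
#' @export
read_rds_survey <- function(path, traits = NULL) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path)
  n0 <- nrow(df)
  if (!"id" %in% names(df)) stop("survey file needs an `id` column", call. = FALSE)

  if (!"recruiter_id" %in% names(df)) {
    coupon_cols <- grep("^coupon_[0-9]+$", names(df), value = TRUE)
    if (!"own_coupon" %in% names(df) || length(coupon_cols) == 0) {
      stop("survey file needs `recruiter_id` or coupon columns", call. = FALSE)
    }
    issued <- unlist(lapply(coupon_cols, function(cc) {
      stats::setNames(as.character(df[[cc]]), df$id)
    }))
    issued <- issued[!is.na(issued) & issued != ""]
    if (anyDuplicated(issued)) {
      stop("coupon issued by more than one respondent: ",
        paste(unique(issued[duplicated(issued)]), collapse = ", "),
        call. = FALSE
      )
    }
    own <- as.character(df$own_coupon)
    df$recruiter_id <- names(issued)[match(own, issued)]
  }

  # eligibility screen
  n_inelig <- 0L
  if (all(c("sex_with_man", "prefer_women_only") %in% names(df))) {
    eligible <- df$sex_with_man == 1 |
      (df$sex_with_man == 0 & df$prefer_women_only == 0)
    eligible[is.na(eligible)] <- FALSE
    n_inelig <- sum(!eligible)
    # a recruit of an ineligible respondent keeps its link to the
    # nearest eligible ancestor removed; reattach as seed
    dropped_ids <- df$id[!eligible]
    df <- df[eligible, , drop = FALSE]
    df$recruiter_id[df$recruiter_id %in% dropped_ids] <- NA
  }

  line <- seq_len(nrow(df)) + 1L # header line offset
  bad <- rep(FALSE, nrow(df))
  reasons <- character(0)
  flag <- function(cond, why) {
    if (any(cond, na.rm = TRUE)) {
      i <- which(cond)
      reasons <<- c(reasons, sprintf(
        "%s (line %s)", why,
        paste(line[i], collapse = ",")
      ))
      bad[i] <<- TRUE
    }
  }
  flag(is.na(df$degree) | df$degree < 1, "degree < 1")
  if ("age" %in% names(df)) flag(!is.na(df$age) & df$age < 18, "age < 18")
  not_seed <- !is.na(df$recruiter_id) & df$recruiter_id != ""
  flag(not_seed & !(df$recruiter_id %in% df$id), "unknown recruiter id")

  if (sum(bad) > 0.05 * max(nrow(df), 1)) {
    stop(
      "more than 5% of rows invalid: ", paste(reasons, collapse = "; "),
      call. = FALSE
    )
  }
  if (any(bad)) {
    warning("dropped invalid rows: ", paste(reasons, collapse = "; "),
      call. = FALSE
    )
    dropped_ids <- df$id[bad]
    df <- df[!bad, , drop = FALSE]
    df$recruiter_id[df$recruiter_id %in% dropped_ids] <- NA
  }

  out <- rds_sample(df, traits = traits)
  attr(out, "n_ineligible") <- n_inelig
  attr(out, "n_dropped") <- sum(bad)
  out
}

resolve_count <- function(count, min_spacing_days = 3) {
  if (inherits(count, "count_result")) {
    return(count)
  }
  if (is.numeric(count)) {
    return(provider_count(count))
  }
  stopifnot(is.list(count))
  method <- count$method %||% "provider"
  switch(method,
    provider = provider_count(count$value,
      period_days = count$period_days %||% 30
    ),
    dedup = dedup_count(
      if (inherits(count$log, "activity_log")) {
        count$log
      } else {
        read_activity_log(count$log)
      },
      min_appearances = count$min_appearances %||% 2,
      min_spacing_days = count$min_spacing_days %||% min_spacing_days
    ),
    capture_recapture = capture_recapture_count(
      if (length(count$capture1) == 1 && file.exists(count$capture1)) {
        readLines(count$capture1)
      } else {
        count$capture1
      },
      if (length(count$capture2) == 1 && file.exists(count$capture2)) {
        readLines(count$capture2)
      } else {
        count$capture2
      },
      correction = count$correction %||% "lincoln_petersen"
    ),
    stop("unknown count method `", method, "`", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full provincial estimation pipeline
#'
#' Executes count -> proportion (both estimators) -> diagnostics ->
#' estimator selection -> multiplier for one province and returns a
#' report bundle; optionally writes the report as JSON plus a one-row
#' CSV mirroring the provincial reporting table, and a run manifest.
#' Any stage's unreliable flag propagates into the report instead of
#' aborting the run.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `province`; `survey` (path, data frame or [rds_sample()]);
#'   `count` (a `count_result`, a plain provider number, or a list with
#'   `method` = `"provider"`/`"dedup"`/`"capture_recapture"` and its
#'   inputs); optionally `proportion` (a list or JSON file with
#'   `p_hat` and `ci`, used directly in place of survey estimation);
#'   `trait` (default `"app_30d"`); `pop_size` for Gile's SS
#'   (`"auto"` iterates SS -> multiplier -> SS to a fixed point);
#'   `reps`, `rng_seed`, `tol`, `window_frac`, `sensitivity_bounds`,
#'   `min_spacing_days`; optional `out_dir`.
#' @return list of class `pipeline_report` with the count, both
#'   proportion estimates, the diagnostics report, the selection, the
#'   multiplier estimate and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  province <- config$province %||% NA_character_
  trait <- config$trait %||% "app_30d"
  reps <- config$reps %||% 1000
  rng_seed <- config$rng_seed %||% 1L
  tol <- config$tol %||% 0.02
  window_frac <- config$window_frac %||% 0.25
  sens <- config$sensitivity_bounds %||% c(0.2, 0.8)

  count <- resolve_count(config$count, config$min_spacing_days %||% 3)

  # a pre-computed proportion (list or JSON file with p_hat and
  # optionally ci) bypasses survey estimation entirely
  if (!is.null(config$proportion)) {
    prop <- config$proportion
    if (is.character(prop)) prop <- jsonlite::read_json(prop, simplifyVector = TRUE)
    prop_est <- new_proportion_estimate(
      prop$estimator %||% "external", trait, prop$p_hat,
      prop$ci %||% c(NA_real_, NA_real_), prop$n %||% NA_integer_, 0L
    )
    mult <- multiplier_estimate(count, prop_est, province = province)
    return(structure(
      list(
        province = province, trait = trait, count = count,
        proportion = prop_est, selected_estimator = prop_est$estimator,
        estimate = mult, reliable = TRUE,
        manifest = list(
          package = "appmultiplier",
          version = as.character(utils::packageVersion("appmultiplier")),
          rng_seed = rng_seed, parameters = list(trait = trait)
        )
      ),
      class = "pipeline_report"
    ))
  }

  survey <- if (inherits(config$survey, "rds_sample")) {
    config$survey
  } else {
    read_rds_survey(config$survey)
  }

  p_rdsi <- rds_i_proportion(survey, trait,
    reps = reps,
    rng_seed = rng_seed
  )

  # Gile's SS needs an assumed population size, which in the multiplier
  # design is itself the quantity being estimated; "auto" resolves the
  # circularity by iterating SS -> multiplier until the implied N moves
  # by less than 1%.
  pop_size <- config$pop_size %||% "auto"
  ss_of <- function(n_assumed, do_ci) {
    giles_ss_proportion(survey, trait,
      N = n_assumed, ci = do_ci,
      reps = min(reps, 200), rng_seed = rng_seed + 1L
    )
  }
  p_ss <- tryCatch(
    {
      if (identical(pop_size, "auto")) {
        seed_p <- if (!is.na(p_rdsi$p_hat)) {
          p_rdsi$p_hat
        } else {
          mean(survey[[trait]], na.rm = TRUE)
        }
        n_assumed <- max(round(count$count / max(seed_p, 0.01)), nrow(survey) + 1)
        for (i in seq_len(20)) {
          fit <- ss_of(n_assumed, do_ci = FALSE)
          n_new <- max(round(count$count / max(fit$p_hat, 1e-6)), nrow(survey) + 1)
          if (abs(n_new - n_assumed) < 0.01 * n_assumed) break
          n_assumed <- n_new
        }
        ss_of(n_assumed, do_ci = TRUE)
      } else {
        ss_of(pop_size, do_ci = TRUE)
      }
    },
    error = function(e) {
      new_proportion_estimate("giles_ss", trait, NA_real_,
        c(NA_real_, NA_real_), nrow(survey), 0L,
        reliable = FALSE, notes = conditionMessage(e)
      )
    }
  )

  diag_rep <- diagnose(survey, trait,
    estimator = "rds_i", tol = tol,
    window_frac = window_frac, sensitivity_bounds = sens
  )
  selection <- select_estimator(list(diag_rep))
  chosen <- if (selection$estimator == "rds_i") p_rdsi else p_ss
  chosen_ok <- !is.na(chosen$p_hat) && chosen$reliable
  if (!chosen_ok) { # fall back to the other estimator, flagged
    other <- if (selection$estimator == "rds_i") p_ss else p_rdsi
    if (!is.na(other$p_hat) && other$reliable) chosen <- other
  }
  mult <- tryCatch(
    multiplier_estimate(count, chosen, province = province),
    error = function(e) NULL
  )

  report <- structure(
    list(
      province = province,
      trait = trait,
      count = count,
      proportion_rds_i = p_rdsi,
      proportion_giles_ss = p_ss,
      diagnostics = diag_rep,
      selection = selection,
      selected_estimator = chosen$estimator,
      estimate = mult,
      reliable = chosen_ok && !is.null(mult),
      manifest = list(
        package = "appmultiplier",
        version = as.character(utils::packageVersion("appmultiplier")),
        rng_seed = rng_seed,
        parameters = list(
          trait = trait, reps = reps, tol = tol,
          window_frac = window_frac, sensitivity_bounds = sens,
          pop_size = pop_size,
          min_spacing_days = config$min_spacing_days %||% 3
        )
      )
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_report(report, config$out_dir)
  }
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report_<province>.json` (full bundle) and a one-row
#' `report_<province>.csv` whose columns are a superset of the
#' provincial reporting table: province, 30-day count and method,
#' selected estimator, proportion with CI, population estimate with CI,
#' diagnostic flags and the RNG seed. Deterministic: rerunning with the
#' same config and seed reproduces the files byte for byte.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if missing).
#' @return character vector of the paths written, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^A-Za-z0-9]+", "_", report$province %||% "province")
  json_path <- file.path(dir, paste0("report_", slug, ".json"))
  csv_path <- file.path(dir, paste0("report_", slug, ".csv"))
  ser <- report
  ser$diagnostics$convergence_series <- NULL
  ser$diagnostics$bottleneck_series <- NULL
  jsonlite::write_json(ser, json_path,
    auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE, null = "null"
  )
  row <- data.frame(
    province = report$province,
    count_30d = report$count$count,
    count_method = report$count$method,
    estimator = report$selected_estimator,
    proportion = report$estimate$proportion$p_hat %||% NA_real_,
    prop_lo = (report$estimate$proportion$ci %||% c(NA, NA))[1],
    prop_hi = (report$estimate$proportion$ci %||% c(NA, NA))[2],
    pop_estimate = report$estimate$N_hat %||% NA_real_,
    pop_lo = (report$estimate$ci %||% c(NA, NA))[1],
    pop_hi = (report$estimate$ci %||% c(NA, NA))[2],
    homophily = report$diagnostics$homophily_value,
    converged = report$diagnostics$converged,
    bottleneck_gap = report$diagnostics$bottleneck_gap,
    sensitive = report$diagnostics$sensitive,
    reliable = report$reliable,
    rng_seed = report$manifest$rng_seed
  )
  utils::write.csv(row, csv_path, row.names = FALSE, na = "")
  invisible(c(json_path, csv_path))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$province, "\n")
  print(x$count)
  cat(
    " selected estimator:", x$selected_estimator, "|",
    x$selection$rationale, "\n"
  )
  if (!is.null(x$estimate)) print(x$estimate)
  if (!x$reliable) cat(" ! estimate flagged unreliable\n")
  invisible(x)
}
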