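#' Construct an RDS sample
#'
#' An `rds_sample` is a data frame holding one row per respondent of a
#' respondent-driven sampling (RDS) survey, together with the recruitment
#' forest implied by the recruiter links. Seeds have `recruiter_id = NA`.
#'
#' @param data data frame with columns `id`, `recruiter_id` (NA for
#'   seeds), `degree` (self-reported network size, >= 1) and any number
#'   of binary trait columns; optional columns `seed_id`,
#'   `recruitment_order`, `age`, `province`. `seed_id` and
#'   `recruitment_order` are derived from the links when absent.
#' @param traits character vector naming the binary trait columns. By
#'   default every 0/1 (or NA) column other than the structural ones is
#'   treated as a trait.
#' @return object of class `rds_sample` (a data frame). The recruitment
#'   forest is validated: no duplicate ids, every recruiter is present
#'   and precedes its recruit in `recruitment_order`, no cycles.
#' @export
rds_sample <- function(data, traits = NULL) {
  data <- as.data.frame(data)
  required <- c("id", "recruiter_id", "degree")
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(data$id)) {
    stop("duplicate respondent ids", call. = FALSE)
  }
  if (!is.numeric(data$degree) || any(!is.na(data$degree) & data$degree < 1)) {
    stop("all degrees must be >= 1", call. = FALSE)
  }

  is_seed <- is.na(data$recruiter_id) | data$recruiter_id == ""
  data$recruiter_id[is_seed] <- NA
  idx <- match(data$recruiter_id, data$id)
  if (any(!is_seed & is.na(idx))) {
    bad <- data$id[!is_seed & is.na(idx)]
    stop(
      "recruiter not present in sample for respondent(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }

  # Walk each chain to its seed; bounded by n steps, so a cycle is caught.
  n <- nrow(data)
  seed_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0
    while (!is.na(idx[j])) {
      j <- idx[j]
      steps <- steps + 1
      if (steps > n) stop("cycle in recruiter links", call. = FALSE)
    }
    seed_of[i] <- j
  }
  data$seed_id <- data$id[seed_of]

  if (is.null(data$recruitment_order)) {
    data$recruitment_order <- seq_len(n)
  }
  bad_order <- !is.na(idx) &
    data$recruitment_order[idx] >= data$recruitment_order
  if (any(bad_order)) {
    stop("recruiter must precede recruit in recruitment_order",
      call. = FALSE
    )
  }

  structural <- c(
    "id", "recruiter_id", "seed_id", "recruitment_order",
    "degree", "age", "province"
  )
  if (is.null(traits)) {
    cand <- setdiff(names(data), structural)
    traits <- cand[vapply(
      cand,
      function(v) {
        x <- data[[v]]
        is.numeric(x) && all(x %in% c(0, 1) | is.na(x))
      },
      logical(1)
    )]
  } else {
    miss <- setdiff(traits, names(data))
    if (length(miss) > 0) {
      stop("trait column(s) not found: ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    for (v in traits) {
      if (!all(data[[v]] %in% c(0, 1) | is.na(data[[v]]))) {
        stop("trait `", v, "` must be binary 0/1 (or NA)", call. = FALSE)
      }
    }
  }

  data <- data[order(data$recruitment_order), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, traits = traits, class = c("rds_sample", "data.frame"))
}

#' @export
print.rds_sample <- function(x, ...) {
  n_seed <- sum(is.na(x$recruiter_id))
  cat(
    "<rds_sample> ", nrow(x), " respondents, ", n_seed, " seeds, traits: ",
    paste(attr(x, "traits"), collapse = ", "), "\n",
    sep = ""
  )
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# Recruiter/recruit pairs for a trait, seeds contributing only as
# recruiters; rows with a missing trait on either end are dropped.
recruitment_pairs <- function(sample, trait) {
  stopifnot(inherits(sample, "rds_sample"))
  if (!trait %in% names(sample)) {
    stop("trait `", trait, "` not found in sample", call. = FALSE)
  }
  idx <- match(sample$recruiter_id, sample$id)
  keep <- !is.na(idx)
  rec_trait <- sample[[trait]][idx[keep]]
  rcr_trait <- sample[[trait]][keep]
  ok <- !is.na(rec_trait) & !is.na(rcr_trait)
  data.frame(recruiter = rec_trait[ok], recruit = rcr_trait[ok])
}

#' Write an RDS sample to CSV
#'
#' @param sample an [rds_sample()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rds_survey <- function(sample, path) {
  stopifnot(inherits(sample, "rds_sample"))
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE, na = "")
  invisible(path)
}
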