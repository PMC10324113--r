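# Canonical exchange formats: the long-format PK CSV, JSON serialisation of
# models / fits / designs, and the trajectory CSV.

.PK_CSV_COLS <- c("subject_id", "group", "body_weight_g", "dose_ng",
                  "time_h", "conc_ng_ml", "blq_flag")

#' Write a PK dataset to the canonical CSV
#'
#' One row per observation with the exact ordered header
#' `subject_id, group, body_weight_g, dose_ng, time_h, conc_ng_ml, blq_flag`.
#' BLQ rows carry an empty `conc_ng_ml`.
#'
#' @param ds A [pk_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(ds, path) {
  stopifnot(inherits(ds, "pk_dataset"))
  rows <- lapply(ds$subjects, function(s) {
    if (!length(s$times)) return(NULL)
    data.frame(subject_id = s$id, group = s$group,
               body_weight_g = s$body_weight, dose_ng = s$dose,
               time_h = s$times, conc_ng_ml = s$conc,
               blq_flag = as.integer(s$blq), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a PK dataset from the canonical CSV
#'
#' Unknown columns are preserved in the parse but ignored; missing required
#' columns raise a schema error naming the column; negative times or doses
#' raise a row-level validation error with the offending line number.
#'
#' @param path CSV file path.
#' @param tau Dosing interval, h.
#' @param lloq Assay LLOQ, ng/mL.
#' @param groups Optional ordered group labels (first = reference);
#'   defaults to order of appearance in the file.
#' @return A [pk_dataset()].
#' @export
read_pk_csv <- function(path, tau = 24, lloq = 0.5, groups = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        group = "character")[
                                          intersect(c("subject_id", "group"),
                                                    .csv_header(path))])
  missing_cols <- setdiff(.PK_CSV_COLS, names(tab))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$time_h) | tab$time_h < 0 |
                 !is.finite(tab$dose_ng) | tab$dose_ng < 0)
  if (length(bad))
    stop("validation error at line(s) ",
         paste(bad + 1L, collapse = ", "),
         ": negative or missing time/dose", call. = FALSE)
  tab$blq_flag <- as.integer(tab$blq_flag)
  ids <- unique(tab$subject_id)
  subs <- lapply(ids, function(id) {
    rr <- tab[tab$subject_id == id, , drop = FALSE]
    pk_subject(id, rr$group[1L], rr$dose_ng[1L], times = rr$time_h,
               conc = rr$conc_ng_ml, blq = rr$blq_flag == 1L,
               body_weight = rr$body_weight_g[1L])
  })
  pk_dataset(subs, tau = tau, groups = groups, lloq = lloq)
}

.csv_header <- function(path) {
  strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
}

# ---- JSON serialisation -------------------------------------------------

.model_to_list <- function(m, assumption_fields = character()) {
  list(theta = as.list(m$theta), groups = m$groups, beta = as.list(m$beta),
       omega = m$omega, error_model = m$error_model,
       error_params = as.list(m$error_params),
       assumptions = as.list(assumption_fields))
}

.list_to_model <- function(x) {
  pk_model(theta = unlist(x$theta), groups = unlist(x$groups),
           beta = unlist(x$beta)[-1L], omega = matrix(unlist(x$omega), 3L),
           error_model = x$error_model,
           error_params = unlist(x$error_params))
}

#' Write a fit result as a structured JSON report
#'
#' @param fit A `pk_fit`.
#' @param path Output JSON path.
#' @param trajectories_csv Optional path for a flat CSV of the parameter
#'   trajectories (one row per iteration).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, trajectories_csv = NULL) {
  stopifnot(inherits(fit, "pk_fit"))
  out <- list(schema = "tacropk/fit/v1",
              model = .model_to_list(fit$model),
              fixed_effects = fit$fixed_effects,
              loglik = fit$loglik, loglik_mc_se = fit$loglik_mc_se,
              aic = fit$aic, bic = fit$bic, npar = fit$npar,
              converged = fit$converged, se_method = fit$se_method,
              acc_rates = fit$acc_rates, seed = fit$seed,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs,
              n_blq_excluded = fit$n_blq_excluded,
              spec = unclass(fit$spec),
              config = unclass(fit$cfg))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor",
                       pretty = TRUE, null = "null")
  if (!is.null(trajectories_csv))
    utils::write.csv(as.data.frame(fit$trajectories), trajectories_csv,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fitted model back from a fit JSON report
#'
#' @param path JSON path written by [write_fit_json()].
#' @return List with `model` (a [pk_model()]) and the report fields.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "tacropk/fit/v1"))
    stop("unrecognised fit report schema", call. = FALSE)
  x$model <- .list_to_model(x$model)
  x
}
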