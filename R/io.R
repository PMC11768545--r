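# CSV schemas of the pipeline:
#   traces : specimen_id, group, load_mg, ph, inactivated, time_s,
#            rel_extension_pct
#   masses : group, replicate, dry_mass_ug, segment_length_mm

trace_columns <- c("specimen_id", "group", "load_mg", "ph", "inactivated",
                   "time_s", "rel_extension_pct")
mass_columns <- c("group", "replicate", "dry_mass_ug", "segment_length_mm")

#' Read a creep-trace table
#'
#' Reads the long-format traces CSV (one row per sampled time point)
#' and checks its schema.
#'
#' @param path CSV file path.
#' @return Data frame with the trace columns.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rep <- validate_trace_table(d)
  if (!all(rep$pass))
    stop("invalid traces file '", path, "': ",
         paste(rep$message[!rep$pass], collapse = "; "), call. = FALSE)
  d$inactivated <- as.logical(d$inactivated)
  d
}

#' Read a dry-mass table
#'
#' @param path CSV file path.
#' @return Data frame with the mass columns.
#' @export
read_masses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rep <- validate_mass_table(d)
  if (!all(rep$pass))
    stop("invalid masses file '", path, "': ",
         paste(rep$message[!rep$pass], collapse = "; "), call. = FALSE)
  d
}

check_row <- function(check, pass, message = "ok") {
  data.frame(check = check, pass = pass,
             message = if (pass) "ok" else message)
}

validate_trace_table <- function(d) {
  miss <- setdiff(trace_columns, names(d))
  out <- check_row("columns", length(miss) == 0L,
                   paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(miss)) return(out)
  out <- rbind(out,
    check_row("numeric", is.numeric(d$time_s) &&
                is.numeric(d$rel_extension_pct) && is.numeric(d$load_mg),
              "time_s, rel_extension_pct and load_mg must be numeric"),
    check_row("finite", all(is.finite(d$time_s)) &&
                all(is.finite(d$rel_extension_pct)),
              "non-finite time or extension values"))
  if (!all(out$pass)) return(out)
  mono <- vapply(split(d$time_s, d$specimen_id),
                 function(t) all(diff(sort(t)) > 0) &&
                   !is.unsorted(t, strictly = TRUE), logical(1))
  out <- rbind(out,
    check_row("times_increasing", all(mono),
              paste("times not strictly increasing for specimen(s):",
                    paste(names(mono)[!mono], collapse = ", "))),
    check_row("min_samples",
              all(table(d$specimen_id) >= 10L),
              "each specimen needs at least 10 samples"))
  out
}

validate_mass_table <- function(d) {
  miss <- setdiff(mass_columns, names(d))
  out <- check_row("columns", length(miss) == 0L,
                   paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(miss)) return(out)
  rbind(out,
    check_row("positive_mass",
              is.numeric(d$dry_mass_ug) && all(d$dry_mass_ug > 0),
              "dry_mass_ug must be positive"),
    check_row("positive_length",
              is.numeric(d$segment_length_mm) &&
                all(d$segment_length_mm > 0),
              "segment_length_mm must be positive"),
    check_row("replication",
              all(table(d$group) >= 2L),
              "each group needs >= 2 replicates"))
}

#' Validate input files against the pipeline schemas
#'
#' Diagnostic schema check of the traces and masses CSVs: required
#' columns, numeric types, strictly increasing time stamps per
#' specimen, minimum replication.  Always returns a report rather than
#' erroring, so it can drive a validation exit path.
#'
#' @param traces_path,masses_path file paths; either may be `NULL` to
#'   skip.
#' @return Data frame with columns `file`, `check`, `pass`, `message`.
#' @export
validate_inputs <- function(traces_path = NULL, masses_path = NULL) {
  out <- list()
  check_file <- function(path, validator, label) {
    if (!file.exists(path))
      return(cbind(file = label, check_row("exists", FALSE,
                                           paste("file not found:", path))))
    d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    NULL)
    if (is.null(d))
      return(cbind(file = label,
                   check_row("parse", FALSE, "could not parse CSV")))
    cbind(file = label, validator(d))
  }
  if (!is.null(traces_path))
    out$traces <- check_file(traces_path, validate_trace_table, "traces")
  if (!is.null(masses_path))
    out$masses <- check_file(masses_path, validate_mass_table, "masses")
  if (!length(out)) stop("no input paths given", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
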