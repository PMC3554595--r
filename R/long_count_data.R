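#' Long-format longitudinal count data
#'
#' Constructor and validator for the long-format container used throughout the
#' package: one row per subject-visit, with a subject identifier, a 1-based
#' visit index, the (possibly unequally spaced) observation time, a binary
#' group/dose covariate, and the observed response.
#'
#' @param subject_id integer vector of subject labels.
#' @param visit integer visit index, 1-based, unique within subject.
#' @param time numeric observation times, non-decreasing within subject.
#' @param group binary (0/1) covariate, constant within subject.
#' @param count response; non-negative integers on the `"count"` scale, or
#'   real values when `scale_flag = "arcsinh"`.
#' @param scale_flag either `"count"` (default) or `"arcsinh"`, marking whether
#'   the response column holds raw counts or transformed values.
#'
#' @return A `data.frame` of class `long_count_data` with columns
#'   `subject_id`, `visit`, `time`, `group`, `count` and attribute
#'   `scale_flag`.
#' @export
long_count_data <- function(subject_id, visit, time, group, count,
                            scale_flag = c("count", "arcsinh")) {
  scale_flag <- match.arg(scale_flag)
  n <- length(subject_id)
  stopifnot(length(visit) == n, length(time) == n,
            length(group) == n, length(count) == n)
  d <- data.frame(subject_id = as.integer(subject_id),
                  visit = as.integer(visit),
                  time = as.numeric(time),
                  group = as.integer(group),
                  count = as.numeric(count))
  validate_long_count_data(d, scale_flag)
  attr(d, "scale_flag") <- scale_flag
  class(d) <- c("long_count_data", "data.frame")
  d
}

validate_long_count_data <- function(d, scale_flag) {
  if (any(!d$group %in% c(0L, 1L)))
    stop("group must be binary 0/1")
  if (scale_flag == "count") {
    if (any(d$count < 0) || any(d$count != round(d$count)))
      stop("counts must be non-negative integers on the count scale")
  }
  sp <- split(d, d$subject_id)
  for (s in sp) {
    if (anyDuplicated(s$visit))
      stop("duplicated (subject_id, visit) pair for subject ", s$subject_id[1])
    if (is.unsorted(s$time[order(s$visit)]))
      stop("times must be non-decreasing within subject ", s$subject_id[1])
    if (length(unique(s$group)) > 1L)
      stop("group must be constant within subject ", s$subject_id[1])
  }
  invisible(d)
}

#' @export
print.long_count_data <- function(x, ...) {
  cat(sprintf("long_count_data: %d observations, %d subjects, scale = %s\n",
              nrow(x), length(unique(x$subject_id)), attr(x, "scale_flag")))
  NextMethod()
}

#' Read / write long-format count data as CSV
#'
#' Plain-text interchange with header `subject_id,visit,time,group,count`.
#'
#' @param file path to a CSV file.
#' @param data a [long_count_data()] object.
#' @return `read_long_count` returns a `long_count_data`; `write_long_count`
#'   returns `file` invisibly.
#' @export
read_long_count <- function(file) {
  d <- utils::read.csv(file)
  long_count_data(d$subject_id, d$visit, d$time, d$group, d$count)
}

#' @rdname read_long_count
#' @export
write_long_count <- function(data, file) {
  utils::write.csv(as.data.frame(data)[, c("subject_id", "visit", "time",
                                           "group", "count")],
                   file, row.names = FALSE)
  invisible(file)
}
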