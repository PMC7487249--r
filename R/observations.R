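#' Nonchronological observation sets
#'
#' A nonchronological data set holds one row per individual: its age at
#' the (single) time of observation and its size at that age, with no
#' growth history. `observation_set()` validates and builds the
#' container, a `data.frame` with columns `age` and `size`.
#'
#' @param age ages in years, strictly positive.
#' @param size sizes (e.g. mean tree height in metres), strictly
#'   positive, same length as `age`.
#' @return A `data.frame` of class `c("observation_set", "data.frame")`.
#' @examples
#' obs <- observation_set(age = c(15, 40, 80), size = c(6.1, 14.9, 21.0))
#' @export
observation_set <- function(age, size) {
  if (length(age) != length(size))
    stop("'age' and 'size' must have the same length", call. = FALSE)
  if (length(age) < 1L) stop("need at least one observation", call. = FALSE)
  .check_pos(age, "age"); .check_pos(size, "size")
  structure(data.frame(age = as.numeric(age), size = as.numeric(size)),
            class = c("observation_set", "data.frame"))
}

#' Read a nonchronological data set from a delimited text file
#'
#' Expects a header naming the age and size columns. Rows with missing
#' or non-positive values are dropped with a row-numbered warning; extra
#' columns are ignored with a notice.
#'
#' @param path path to a CSV file.
#' @param age_col,size_col column names holding age and size.
#' @return An [observation_set()].
#' @export
read_observations <- function(path, age_col = "age", size_col = "size") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c(age_col, size_col) %in% names(df)))
    stop(sprintf("file '%s' lacks required columns '%s' and '%s'",
                 path, age_col, size_col), call. = FALSE)
  extra <- setdiff(names(df), c(age_col, size_col))
  if (length(extra))
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  age <- suppressWarnings(as.numeric(df[[age_col]]))
  size <- suppressWarnings(as.numeric(df[[size_col]]))
  bad <- which(is.na(age) | is.na(size) | age <= 0 | size <= 0)
  if (length(bad)) {
    warning(sprintf("dropping %d invalid row(s) (non-positive or missing age/size): %s",
                    length(bad), paste(bad, collapse = ", ")),
            call. = FALSE)
    age <- age[-bad]; size <- size[-bad]
  }
  if (!length(age))
    stop(sprintf("file '%s' contains no valid observations", path),
         call. = FALSE)
  observation_set(age, size)
}

#' @rdname read_observations
#' @param obs an [observation_set()].
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  # 17 significant digits so write -> read round-trips exactly
  utils::write.csv(data.frame(age = sprintf("%.17g", obs$age),
                              size = sprintf("%.17g", obs$size)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
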