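#' Column-dialect for delimited epoch and observation files
#'
#' Describes the separator and the header names (candidates, matched in
#' order) used by [read_count_epochs()] and [read_sofit_log()].
#'
#' @param sep field separator.
#' @param participant,session,offset,vertical,vm,axis2,axis3,interval,category,valid
#'   character vectors of acceptable header names for each field.
#' @return a list of class `file_dialect`.
#' @export
file_dialect <- function(sep = ",",
                         participant = c("participant", "id"),
                         session = "session",
                         offset = c("offset_s", "offset"),
                         vertical = c("vertical_counts", "axis1", "vertical"),
                         vm = c("vm_counts", "vm", "vector_magnitude"),
                         axis2 = "axis2", axis3 = "axis3",
                         interval = "interval",
                         category = c("category", "sofit", "code"),
                         valid = "valid") {
  structure(list(sep = sep, participant = participant, session = session,
                 offset = offset, vertical = vertical, vm = vm,
                 axis2 = axis2, axis3 = axis3, interval = interval,
                 category = category, valid = valid),
            class = "file_dialect")
}

# first header in `candidates` present in `nms`, or NA
match_col <- function(nms, candidates) {
  hit <- candidates[candidates %in% nms]
  if (length(hit)) hit[1] else NA_character_
}

#' Read 10-s accelerometer count epochs from delimited text
#'
#' Expects a header and one row per 10-s epoch with participant, session
#' and epoch start offset (seconds), plus either a vertical + vector
#' magnitude column pair or three raw axis columns.  With three axes,
#' the vector magnitude is the Euclidean norm of the axes, rounded per
#' 10-s epoch.  Rows are returned sorted by participant then offset
#' (re-sorting out-of-order input with a warning); rows with
#' non-numeric/missing fields are dropped with a warning naming their
#' line numbers; negative counts are an error naming the row.
#'
#' @param path file path.
#' @param dialect a [file_dialect()].
#' @return data frame with columns `participant`, `session`, `offset_s`,
#'   `vertical_counts`, `vm_counts`.
#' @export
read_count_epochs <- function(path, dialect = file_dialect()) {
  assert_that(file.exists(path), "file not found: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  nms <- names(raw)
  pcol <- match_col(nms, dialect$participant)
  scol <- match_col(nms, dialect$session)
  ocol <- match_col(nms, dialect$offset)
  vcol <- match_col(nms, dialect$vertical)
  mcol <- match_col(nms, dialect$vm)
  a2 <- match_col(nms, dialect$axis2); a3 <- match_col(nms, dialect$axis3)
  missing_cols <- c(participant = pcol, session = scol, offset = ocol,
                    vertical = vcol)
  assert_that(!anyNA(missing_cols), "missing required column(s): ",
              paste(names(missing_cols)[is.na(missing_cols)], collapse = ", "))
  assert_that(!is.na(mcol) || (!is.na(a2) && !is.na(a3)),
              "need either a vector-magnitude column or three axis columns")
  if (nrow(raw) == 0) {
    warning("empty epoch-count file: ", path, call. = FALSE)
    return(data.frame(participant = character(), session = integer(),
                      offset_s = integer(), vertical_counts = integer(),
                      vm_counts = integer()))
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  offset <- num(ocol); vertical <- num(vcol)
  vm <- if (!is.na(mcol)) num(mcol)
        else round(sqrt(vertical^2 + num(a2)^2 + num(a3)^2))
  bad <- !is.finite(offset) | !is.finite(vertical) | !is.finite(vm) |
    is.na(raw[[pcol]])
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  keep <- which(!bad)
  neg <- keep[vertical[keep] < 0 | vm[keep] < 0]
  assert_that(length(neg) == 0, "negative counts at line(s): ",
              paste(neg + 1L, collapse = ", "))
  out <- data.frame(participant = as.character(raw[[pcol]][keep]),
                    session = raw[[scol]][keep],
                    offset_s = as.integer(offset[keep]),
                    vertical_counts = as.integer(round(vertical[keep])),
                    vm_counts = as.integer(round(vm[keep])))
  ord <- order(out$participant, out$offset_s)
  if (!identical(ord, seq_len(nrow(out)))) {
    warning("rows out of time order; reordered by participant and offset",
            call. = FALSE)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a direct-observation (SOFIT) coding log from delimited text
#'
#' One row per 20-s interval with participant, session, 0-based interval
#' index and the recorded category (1-5).  A `valid` column (logical) is
#' optional; when absent every record is treated as valid.  Categories
#' outside 1-5 and duplicate (participant, session, interval) rows are
#' errors naming the offending line.
#'
#' @inheritParams read_count_epochs
#' @return data frame with columns `participant`, `session`, `interval`,
#'   `category`, `valid`.
#' @export
read_sofit_log <- function(path, dialect = file_dialect()) {
  assert_that(file.exists(path), "file not found: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  nms <- names(raw)
  pcol <- match_col(nms, dialect$participant)
  scol <- match_col(nms, dialect$session)
  icol <- match_col(nms, dialect$interval)
  ccol <- match_col(nms, dialect$category)
  vcol <- match_col(nms, dialect$valid)
  need <- c(participant = pcol, session = scol, interval = icol,
            category = ccol)
  assert_that(!anyNA(need), "missing required column(s): ",
              paste(names(need)[is.na(need)], collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty observation log: ", path, call. = FALSE)
    return(data.frame(participant = character(), session = integer(),
                      interval = integer(), category = integer(),
                      valid = logical()))
  }
  category <- suppressWarnings(as.integer(raw[[ccol]]))
  bad_cat <- which(is.na(category) | category < 1L | category > 5L)
  assert_that(length(bad_cat) == 0,
              "observation category outside 1..5 at line(s): ",
              paste(bad_cat + 1L, collapse = ", "))
  key <- paste(raw[[pcol]], raw[[scol]], raw[[icol]])
  dup <- which(duplicated(key))
  assert_that(length(dup) == 0,
              "duplicate (participant, interval) record at line(s): ",
              paste(dup + 1L, collapse = ", "))
  valid <- if (!is.na(vcol)) as.logical(raw[[vcol]]) else rep(TRUE, nrow(raw))
  data.frame(participant = as.character(raw[[pcol]]),
             session = raw[[scol]],
             interval = as.integer(raw[[icol]]),
             category = category,
             valid = valid)
}
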