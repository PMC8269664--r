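#' ROI time-series container
#'
#' Wraps one subject's BOLD matrix (rows = time points, columns = regions)
#' together with its subject identifier and optional repetition time.
#'
#' @param values Numeric matrix, M time points x R regions. All entries must
#'   be finite; M >= 2 and R >= 2.
#' @param subject_id Character scalar identifying the subject.
#' @param repetition_time Optional TR in seconds (metadata only).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id = "subject",
                           repetition_time = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("time-series values must be numeric")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("time series needs at least 2 time points and 2 regions, got ",
         nrow(values), " x ", ncol(values))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite value at row %d, column %d", bad[1, 1], bad[1, 2]))
  }
  structure(
    list(values = values, subject_id = as.character(subject_id),
         repetition_time = repetition_time),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject '%s': %d time points x %d regions\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' Read a subject's ROI time series from delimited text
#'
#' Rows are time points, columns are regions; no header is expected. Columns
#' are kept in file order: region index is positional (1-based in all
#' user-facing reports).
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field separator; `","` by default, use `"\t"` for TSV and
#'   `""` for whitespace.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [roi_timeseries()].
#' @export
read_timeseries <- function(path, delimiter = ",", subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty time-series file: ", path)
  split_row <- function(l) {
    if (nzchar(delimiter)) strsplit(l, delimiter, fixed = TRUE)[[1]]
    else strsplit(trimws(l), "[[:space:]]+")[[1]]
  }
  rows <- lapply(lines, split_row)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf(
      "non-rectangular table in %s: row %d has %d fields, row 1 has %d",
      path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1], ncols[1]))
  }
  values <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                   nrow = length(rows), byrow = TRUE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite or non-numeric value at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  roi_timeseries(values, subject_id = subject_id)
}

#' Write a subject's ROI time series as delimited text
#'
#' @param ts A [roi_timeseries()].
#' @param path Output file path.
#' @param delimiter Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, delimiter = ",") {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$values, path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a headed CSV with columns `subject_id`, `label`, `path`.
#' Labels may be numeric (+1 / -1) or the strings "ASD" / "NC"; they are
#' mapped to +1 (patients) and -1 (controls). Relative paths are resolved
#' against the manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @return A data frame of class `cohort_manifest` with columns
#'   `subject_id` (character), `label` (+1/-1 integer), `path` (character).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns subject_id, label, path; got: ",
         paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("empty cohort")
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         tab$subject_id[duplicated(tab$subject_id)][1])
  }
  tab$label <- map_labels(tab$label)
  rel <- !grepl("^(/|[A-Za-z]:)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  out <- data.frame(subject_id = tab$subject_id, label = tab$label,
                    path = tab$path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

map_labels <- function(x) {
  x <- trimws(as.character(x))
  lab <- rep(NA_integer_, length(x))
  lab[x %in% c("1", "+1", "ASD", "asd")] <- 1L
  lab[x %in% c("-1", "NC", "nc")] <- -1L
  if (anyNA(lab)) {
    stop("label outside the two-class vocabulary {+1/ASD, -1/NC}: ",
         x[is.na(lab)][1])
  }
  lab
}

#' Write a cohort manifest
#'
#' @param manifest A `cohort_manifest` or data frame with columns
#'   `subject_id`, `label`, `path`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("subject_id", "label", "path")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Network matrix container
#'
#' A square symmetric matrix tagged with the kind of network it holds
#' (`static` C-FCN, `lodfcn_window`, `cm`, `ho`, `rms`, or `block`) and, for
#' moment-derived networks, the moment order d.
#'
#' @param values Square numeric matrix, symmetric within 1e-10.
#' @param kind One of `"static"`, `"lodfcn_window"`, `"cm"`, `"ho"`, `"rms"`,
#'   `"block"`.
#' @param order_d Integer moment order, or `NULL` when not applicable.
#' @return A matrix of class `network_matrix` carrying `kind`/`order_d`
#'   attributes.
#' @export
network_matrix <- function(values, kind, order_d = NULL) {
  values <- as.matrix(values)
  kind <- match.arg(kind,
                    c("static", "lodfcn_window", "cm", "ho", "rms", "block"))
  if (nrow(values) != ncol(values)) {
    stop("network matrix must be square, got ",
         nrow(values), " x ", ncol(values))
  }
  if (max(abs(values - t(values))) > 1e-10) {
    stop("network matrix must be symmetric (tolerance 1e-10)")
  }
  structure(values, kind = kind,
            order_d = if (is.null(order_d)) NULL else as.integer(order_d),
            class = c("network_matrix", "matrix", "array"))
}

#' @export
print.network_matrix <- function(x, ...) {
  d <- attr(x, "order_d")
  cat(sprintf("<network_matrix> kind=%s%s, %d x %d\n", attr(x, "kind"),
              if (is.null(d)) "" else paste0(" d=", d), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

network_kind <- function(net) attr(net, "kind")
network_order <- function(net) attr(net, "order_d")

#' Write a network matrix to delimited text
#'
#' The file starts with a single `#` header line recording kind, moment order
#' and size, followed by one comma-separated row per region, so stored
#' networks are diff-able and language neutral.
#'
#' @param net A [network_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "network_matrix"))
  d <- attr(net, "order_d")
  header <- sprintf("# kind=%s order_d=%s R=%d", attr(net, "kind"),
                    if (is.null(d)) "NA" else d, nrow(net))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(unclass(net), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a network matrix written by [write_network()]
#'
#' @param path Path to a network file with a `#` metadata header.
#' @return A [network_matrix()]; kind and order are restored from the header.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing '#' header line in ", path)
  get_field <- function(name) {
    m <- regmatches(header, regexpr(paste0(name, "=[^ ]+"), header))
    if (length(m) == 0L) stop("header missing field '", name, "' in ", path)
    sub(paste0(name, "="), "", m)
  }
  kind <- get_field("kind")
  d <- get_field("order_d")
  d <- if (d == "NA") NULL else as.integer(d)
  values <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                        colClasses = "numeric"))
  dimnames(values) <- NULL
  r <- as.integer(get_field("R"))
  if (nrow(values) != r || ncol(values) != r) {
    stop(sprintf("network in %s is %d x %d but header declares R=%d",
                 path, nrow(values), ncol(values), r))
  }
  network_matrix(values, kind = kind, order_d = d)
}
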