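#' Construct a persons x covariates sparse feature matrix
#'
#' The standardized container every pipeline stage consumes: a sparse numeric
#' matrix whose rows are persons and whose columns are covariates (mostly
#' binary presence indicators extracted from clinical records). Absent
#' (person, covariate) pairs are semantic zeros. Row and column identifiers
#' are opaque strings, kept sorted for determinism.
#'
#' @param person_id character or integer vector of person identifiers.
#' @param covariate_id character or integer vector of covariate identifiers,
#'   same length as \code{person_id}.
#' @param value numeric vector of finite values (binary indicators for most
#'   covariates; nonnegative reals for measurement-like features).
#' @param persons,covariates optional full id universes; defaults to the ids
#'   observed in the records. Needed to represent all-zero rows/columns.
#' @return a \code{\link[Matrix]{dgCMatrix}} with sorted person row names and
#'   covariate column names, classed as \code{feature_matrix}.
#' @export
feature_matrix <- function(person_id, covariate_id, value,
                           persons = NULL, covariates = NULL) {
  person_id <- as.character(person_id)
  covariate_id <- as.character(covariate_id)
  value <- as.numeric(value)
  if (length(person_id) != length(covariate_id) ||
      length(person_id) != length(value))
    stop_fmt("person_id, covariate_id and value must have equal length")
  if (length(value) && any(!is.finite(value)))
    stop_fmt("non-finite value at record %d", which(!is.finite(value))[1])
  key <- paste(person_id, covariate_id, sep = "\r")
  if (anyDuplicated(key))
    stop_fmt("duplicate (person_id, covariate_id) pair: (%s, %s)",
             person_id[anyDuplicated(key)], covariate_id[anyDuplicated(key)])
  persons <- sort(unique(c(as.character(persons %||% character()), person_id)))
  covariates <- sort(unique(c(as.character(covariates %||% character()),
                              covariate_id)))
  m <- Matrix::sparseMatrix(
    i = match(person_id, persons),
    j = match(covariate_id, covariates),
    x = value,
    dims = c(length(persons), length(covariates)),
    dimnames = list(persons, covariates))
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  structure_feature_matrix(m)
}

structure_feature_matrix <- function(m) {
  stopifnot(is(m, "sparseMatrix"))
  m <- as(Matrix::drop0(m), "CsparseMatrix")
  if (is.null(rownames(m))) {
    if (nrow(m) > 0)
      stop_fmt("feature matrix requires person row names")
    rownames(m) <- character()
  }
  if (is.null(colnames(m))) {
    if (ncol(m) > 0)
      stop_fmt("feature matrix requires covariate column names")
    colnames(m) <- character()
  }
  if (anyDuplicated(rownames(m))) stop_fmt("duplicate person ids")
  if (anyDuplicated(colnames(m))) stop_fmt("duplicate covariate ids")
  m
}

#' Read a feature table from disk
#'
#' Two plain-text dialects are supported. \code{long_csv} is the canonical
#' interchange: a CSV with header \code{person_id,covariate_id,value}, one
#' nonzero cell per row. \code{matrix_market} reads a coordinate MatrixMarket
#' file plus two sidecar id lists (\code{<path>.rows}, \code{<path>.cols}, one
#' id per line).
#'
#' @param path file path.
#' @param format \code{"long_csv"} (default) or \code{"matrix_market"}.
#' @return a \code{feature_matrix} (sparse matrix with id dimnames), rows and
#'   columns sorted by id.
#' @export
read_feature_table <- function(path, format = c("long_csv", "matrix_market")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (format == "long_csv") {
    df <- utils::read.csv(path, colClasses = c("character", "character", "character"))
    if (!identical(names(df), c("person_id", "covariate_id", "value")))
      stop_fmt("expected header person_id,covariate_id,value in %s", path)
    if (nrow(df) == 0)
      return(feature_matrix(character(), character(), numeric()))
    val <- suppressWarnings(as.numeric(df$value))
    if (any(is.na(val)))
      stop_fmt("non-numeric value at line %d of %s",
               which(is.na(val))[1] + 1L, path)
    bad <- !nzchar(df$person_id) | !nzchar(df$covariate_id)
    if (any(bad)) stop_fmt("malformed row at line %d of %s", which(bad)[1] + 1L, path)
    feature_matrix(df$person_id, df$covariate_id, val)
  } else {
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop_fmt("sidecar id lists %s / %s not found", rows_path, cols_path)
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    rn <- readLines(rows_path)
    cn <- readLines(cols_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_fmt("sidecar id lists do not match matrix dimensions in %s", path)
    dimnames(m) <- list(rn, cn)
    m <- m[order(rn), order(cn), drop = FALSE]
    structure_feature_matrix(m)
  }
}

#' Write a feature table to disk
#'
#' Inverse of \code{\link{read_feature_table}}: \code{long_csv} rows are
#' emitted sorted by (person_id, covariate_id) so output is diff-friendly and
#' byte-stable; \code{matrix_market} writes a standard coordinate MTX file
#' plus the two sidecar id lists. Since the long format stores only nonzero
#' cells, persons or covariates whose values are all zero are not
#' representable in \code{long_csv} (they drop from the round trip); use
#' \code{matrix_market}, whose sidecar id lists keep full dimensions, when
#' that matters.
#'
#' @param m a \code{feature_matrix}.
#' @inheritParams read_feature_table
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(m, path, format = c("long_csv", "matrix_market")) {
  format <- match.arg(format)
  m <- structure_feature_matrix(m)
  if (format == "long_csv") {
    tm <- as(m, "TsparseMatrix")
    pid <- as.character(rownames(m))[tm@i + 1L]
    cid <- as.character(colnames(m))[tm@j + 1L]
    ord <- order(pid, cid)
    df <- data.frame(person_id = pid[ord], covariate_id = cid[ord],
                     value = format(tm@x[ord], scientific = FALSE, trim = TRUE))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("person_id,covariate_id,value", con)
    if (nrow(df))
      writeLines(paste(df$person_id, df$covariate_id, df$value, sep = ","), con)
  } else {
    Matrix::writeMM(m, path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read / write outcome labels
#'
#' Labels CSV has header \code{person_id,outcome} with outcome in \{0,1\}.
#'
#' @param path file path.
#' @return named integer vector of 0/1 outcomes, names = person ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  if (!identical(names(df), c("person_id", "outcome")))
    stop_fmt("expected header person_id,outcome in %s", path)
  y <- suppressWarnings(as.integer(df$outcome))
  if (any(is.na(y) | !(y %in% c(0L, 1L))))
    stop_fmt("outcome must be 0 or 1 in %s", path)
  if (anyDuplicated(df$person_id)) stop_fmt("duplicate person_id in %s", path)
  stats::setNames(y, df$person_id)
}

#' @rdname read_labels
#' @param labels named 0/1 vector.
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0, 1)))
  ord <- order(names(labels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("person_id,outcome", con)
  writeLines(paste(names(labels)[ord], as.integer(labels)[ord], sep = ","), con)
  invisible(path)
}

#' Assemble one site's dataset with a 7:1:2 patient-level split
#'
#' Persons are assigned at random (uniformly, without outcome stratification)
#' to train / tune / test partitions with deterministic counts
#' \code{floor(0.7 n)}, \code{floor(0.1 n)} and the remainder, matching the
#' patient-basis split used for model development. Assignment is reproducible
#' given \code{seed}.
#'
#' @param features \code{feature_matrix} for the site.
#' @param labels named 0/1 vector covering every person in \code{features}.
#' @param seed integer seed for the split.
#' @param site_id site identifier string.
#' @return a \code{site_dataset}: list with \code{site_id}, \code{features},
#'   \code{labels}, and \code{split} (factor train/tune/test per person).
#' @export
split_site <- function(features, labels, seed, site_id = "site") {
  features <- structure_feature_matrix(features)
  persons <- rownames(features)
  n <- length(persons)
  if (n < 10) stop_fmt("need at least 10 persons to populate all splits (got %d)", n)
  if (!all(persons %in% names(labels)))
    stop_fmt("labels missing for %d person(s), e.g. %s",
             sum(!(persons %in% names(labels))),
             persons[!(persons %in% names(labels))][1])
  labels <- labels[persons]
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be 0/1")
  n_train <- floor(0.7 * n)
  n_tune <- floor(0.1 * n)
  perm <- with_seed(seed, sample.int(n))
  split <- factor(rep("test", n), levels = c("train", "tune", "test"))
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_tune)]] <- "tune"
  names(split) <- persons
  site_dataset(site_id, features, labels, split)
}

#' @rdname split_site
#' @param split factor/character per-person assignment to train/tune/test.
#' @export
site_dataset <- function(site_id, features, labels, split) {
  features <- structure_feature_matrix(features)
  persons <- rownames(features)
  labels <- labels[persons]
  split <- factor(as.character(split[persons]), levels = c("train", "tune", "test"))
  if (anyNA(labels) || anyNA(split))
    stop_fmt("labels/split must cover every person in site %s", site_id)
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be 0/1")
  structure(list(site_id = as.character(site_id), features = features,
                 labels = stats::setNames(as.integer(labels), persons),
                 split = stats::setNames(split, persons)),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset '%s'>: %d persons x %d covariates, %d outcomes (%.2f%%)\n",
              x$site_id, nrow(x$features), ncol(x$features), sum(x$labels),
              100 * mean(x$labels)))
  cat("  split:", paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                        collapse = ", "), "\n")
  invisible(x)
}

## Subset a site's rows by partition ("train", "tune", "test", or "all").
site_partition <- function(site, which = c("train", "tune", "test", "all")) {
  which <- match.arg(which)
  keep <- if (which == "all") rep(TRUE, length(site$split)) else site$split == which
  list(x = site$features[keep, , drop = FALSE],
       y = site$labels[keep])
}

#' Bundle development clients and an optional external validation site
#'
#' @param clients list of \code{site_dataset} (development sites).
#' @param external optional \code{site_dataset} held out entirely for
#'   external validation (never contributes training rows).
#' @return a \code{federation_dataset}.
#' @export
federation_dataset <- function(clients, external = NULL) {
  stopifnot(length(clients) >= 1, all(vapply(clients, inherits, TRUE, "site_dataset")))
  ids <- vapply(clients, `[[`, "", "site_id")
  if (!is.null(external)) ids <- c(ids, external$site_id)
  if (anyDuplicated(ids)) stop_fmt("site_ids must be unique")
  names(clients) <- vapply(clients, `[[`, "", "site_id")
  structure(list(clients = clients, external = external),
            class = "federation_dataset")
}

#' @export
print.federation_dataset <- function(x, ...) {
  cat(sprintf("<federation_dataset>: %d development site(s)%s\n",
              length(x$clients),
              if (is.null(x$external)) "" else sprintf(" + external '%s'", x$external$site_id)))
  for (cl in x$clients) print(cl)
  if (!is.null(x$external)) print(x$external)
  invisible(x)
}
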