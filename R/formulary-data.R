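#' @keywords internal
"_PACKAGE"

# ---- validation helpers ----------------------------------------------------

check_binary <- function(M, what = "matrix") {
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(M))
    stop(sprintf(
      "%s contains a non-binary cell at row '%s', column '%s' (value %s)",
      what,
      if (is.null(rownames(M))) ij[1] else rownames(M)[ij[1]],
      if (is.null(colnames(M))) ij[2] else colnames(M)[ij[2]],
      format(M[bad[1]])
    ), call. = FALSE)
  }
  invisible(M)
}

check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

# ---- constructors -----------------------------------------------------------

#' Construct a binary formula-by-plant usage matrix
#'
#' The central data object of the package: an I x J matrix whose cell
#' \code{(i, j)} is 1 when formula \code{i} lists plant \code{j} among its
#' ingredients and 0 otherwise.  Mixing ratios are not represented; commercial
#' formula registrations typically state only the ingredient list, so the
#' presence--absence coding is the natural resolution of the data.
#'
#' @param X numeric matrix with entries in \{0, 1\}.
#' @param formula_ids,plant_ids character identifiers; default to the
#'   dimnames of \code{X}.
#' @return A \code{usage_matrix}: a base matrix with unique dimnames and a
#'   class attribute.
#' @export
usage_matrix <- function(X, formula_ids = rownames(X), plant_ids = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(formula_ids)) formula_ids <- paste0("F", seq_len(nrow(X)))
  if (is.null(plant_ids))   plant_ids   <- paste0("P", seq_len(ncol(X)))
  stopifnot(nrow(X) >= 1, ncol(X) >= 1,
            length(formula_ids) == nrow(X), length(plant_ids) == ncol(X))
  check_unique_ids(formula_ids, "formula")
  check_unique_ids(plant_ids, "plant")
  dimnames(X) <- list(formula_ids, plant_ids)
  check_binary(X, "usage matrix")
  empty <- colSums(X) == 0
  if (any(empty)) {
    # retained so plant axis stays aligned with any activity annotation
    message(sprintf("usage_matrix: %d plant column(s) with all-zero usage retained: %s",
                    sum(empty), paste(utils::head(plant_ids[empty], 5), collapse = ", ")))
  }
  structure(X, class = c("usage_matrix", class(X)))
}

#' Construct efficacy labels aligned with a usage matrix
#'
#' @param labels character or factor of efficacy class codes, one per formula.
#' @param class_names ordered class set; defaults to the sorted unique labels.
#'   With the canonical Jamu coding this is the 9-class set of
#'   \code{\link{jamu_classes}}.
#' @param formula_ids optional identifiers (same order as the paired usage
#'   matrix).
#' @return factor with levels \code{class_names} and names \code{formula_ids}.
#' @export
efficacy_labels <- function(labels, class_names = NULL, formula_ids = NULL) {
  labels <- as.character(labels)
  if (is.null(class_names)) class_names <- sort(unique(labels))
  unknown <- setdiff(labels, class_names)
  if (length(unknown)) {
    stop(sprintf("unknown efficacy label(s): %s", paste(unique(unknown), collapse = ", ")),
         call. = FALSE)
  }
  f <- factor(labels, levels = class_names)
  if (!is.null(formula_ids)) {
    check_unique_ids(formula_ids, "formula")
    names(f) <- formula_ids
  }
  f
}

#' The nine canonical Jamu efficacy classes
#'
#' Order follows the conventional class listing: urinary-related problems,
#' disorders of appetite, disorders of mood and behavior, gastrointestinal
#' disorders, female reproductive organ problems, musculoskeletal and
#' connective tissue disorders, pain/inflammation, respiratory disease, and
#' wounds and skin infections.
#'
#' @return character vector of length 9.
#' @export
jamu_classes <- function() {
  c("URI", "DOA", "DMB", "GST", "FML", "MSC", "PIN", "RSP", "WND")
}

#' Dummy-code efficacy labels as an indicator response matrix
#'
#' Class membership becomes an I x L indicator matrix Y with
#' \code{Y[i, l] = 1} iff formula i belongs to class l.  Because every formula
#' carries exactly one registered efficacy, each row sums to 1.  Y is the
#' response block for (N-)PLS-DA.
#'
#' @param labels factor or character vector of class codes.
#' @param class_names ordered class set (columns of Y); defaults to the factor
#'   levels.
#' @return I x L binary matrix with class-name columns.
#' @export
to_dummy <- function(labels, class_names = levels(factor(labels))) {
  labels <- efficacy_labels(labels, class_names,
                            formula_ids = names(labels))
  Y <- matrix(0, length(labels), length(class_names),
              dimnames = list(names(labels), class_names))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Construct a plant-by-activity annotation matrix
#'
#' @param A binary J x K matrix; \code{A[j, k] = 1} when plant j is reported
#'   to carry pharmacological activity k.
#' @param plant_ids,activity_ids identifiers; default to dimnames.
#' @return validated \code{activity_matrix}.
#' @export
activity_matrix <- function(A, plant_ids = rownames(A), activity_ids = colnames(A)) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (is.null(plant_ids))    plant_ids    <- paste0("P", seq_len(nrow(A)))
  if (is.null(activity_ids)) activity_ids <- paste0("A", seq_len(ncol(A)))
  stopifnot(length(plant_ids) == nrow(A), length(activity_ids) == ncol(A))
  check_unique_ids(plant_ids, "plant")
  check_unique_ids(activity_ids, "activity")
  dimnames(A) <- list(plant_ids, activity_ids)
  check_binary(A, "activity matrix")
  structure(A, class = c("activity_matrix", class(A)))
}

# ---- tensor -----------------------------------------------------------------

#' Build the formula x plant x activity usage tensor
#'
#' \code{X3[i, j, k] = X[i, j] * A[j, k]}: plant j contributes activity k to
#' formula i only when the formula uses the plant and the plant carries the
#' activity.
#'
#' @param X usage matrix (I x J).
#' @param A activity matrix (J x K); its plant axis must match \code{X}'s
#'   columns exactly (same ids, same order).
#' @return I x J x K binary array with dimnames (formula, plant, activity).
#' @export
build_tensor <- function(X, A) {
  if (!identical(colnames(X), rownames(A))) {
    stop("plant ids of the usage matrix and the activity matrix do not match",
         call. = FALSE)
  }
  I <- nrow(X); J <- ncol(X); K <- ncol(A)
  X3 <- array(0, dim = c(I, J, K),
              dimnames = list(rownames(X), colnames(X), colnames(A)))
  for (k in seq_len(K)) {
    X3[, , k] <- sweep(unclass(X), 2, A[, k], `*`)
  }
  X3
}

#' Matricize (unfold) the usage tensor into an I x JK matrix
#'
#' Frontal slabs are concatenated activity-major: the slab for activity k
#' occupies columns \code{(k-1)*J + 1 ... k*J}.  Under this ordering the
#' trilinear score of an observation equals the inner product of its unfolded
#' row with the Kronecker weight \code{wK \%x\% wJ}.
#'
#' @param X3 I x J x K array.
#' @return I x JK matrix; column names are \code{"<plant>|<activity>"}.
#' @export
matricize <- function(X3) {
  d <- dim(X3)
  stopifnot(length(d) == 3)
  dn <- dimnames(X3)
  M <- X3
  dim(M) <- c(d[1], d[2] * d[3])
  if (!is.null(dn)) {
    rownames(M) <- dn[[1]]
    if (!is.null(dn[[2]]) && !is.null(dn[[3]])) {
      colnames(M) <- as.vector(outer(dn[[2]], dn[[3]], paste, sep = "|"))
    }
  }
  M
}

#' Fold an I x JK matrix back into an I x J x K tensor
#'
#' Inverse of \code{\link{matricize}} for the stated column ordering.
#'
#' @param M I x JK matrix.
#' @param J,K plant and activity dimensions.
#' @param dimnames optional dimnames for the result.
#' @return I x J x K array.
#' @export
fold <- function(M, J, K, dimnames = NULL) {
  stopifnot(ncol(M) == J * K)
  X3 <- as.matrix(M)
  dim(X3) <- c(nrow(M), J, K)
  if (!is.null(dimnames)) dimnames(X3) <- dimnames
  X3
}

# ---- file I/O ---------------------------------------------------------------

#' Read a formulary usage table with an efficacy label column
#'
#' Expected layout: header row of plant ids, first column of formula ids, one
#' row per formula, binary cells, plus one label column (default name
#' \code{"efficacy"}) holding the class code.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param label_col name of the label column.
#' @param class_names ordered class set; defaults to sorted observed labels.
#' @return list with elements \code{usage} (a \code{\link{usage_matrix}}) and
#'   \code{labels} (an \code{\link{efficacy_labels}} factor).
#' @export
read_usage_table <- function(path, sep = "\t", label_col = "efficacy",
                             class_names = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% colnames(df)) {
    stop(sprintf("label column '%s' not found in %s", label_col, path), call. = FALSE)
  }
  labels <- df[[label_col]]
  df[[label_col]] <- NULL
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    stop(sprintf("usage table %s contains non-numeric cells", path), call. = FALSE)
  }
  usage <- usage_matrix(X, formula_ids = rownames(df), plant_ids = colnames(df))
  labels <- efficacy_labels(labels, class_names, formula_ids = rownames(df))
  list(usage = usage, labels = labels)
}

#' Write a formulary usage table (round-trips with \code{read_usage_table})
#'
#' @param usage usage matrix.
#' @param labels efficacy labels aligned with \code{usage}.
#' @param path output path.
#' @param sep field separator.
#' @param label_col name for the label column.
#' @export
write_usage_table <- function(usage, labels, path, sep = "\t",
                              label_col = "efficacy") {
  df <- as.data.frame(unclass(usage), check.names = FALSE)
  df[[label_col]] <- as.character(labels)
  utils::write.table(cbind(formula_id = rownames(usage), df), path,
                     sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a plant-by-activity annotation table
#'
#' @param path file path; header = activity ids, first column = plant ids.
#' @param sep field separator.
#' @return \code{\link{activity_matrix}}.
#' @export
read_activity_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  activity_matrix(as.matrix(df), plant_ids = rownames(df), activity_ids = colnames(df))
}

#' Write a plant-by-activity annotation table
#'
#' @param A activity matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_activity_table <- function(A, path, sep = "\t") {
  utils::write.table(cbind(plant_id = rownames(A),
                           as.data.frame(unclass(A), check.names = FALSE)),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
}
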