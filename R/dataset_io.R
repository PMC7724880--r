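#' Binary drug-disease association matrix
#'
#' Container for the supervision signal: a binary matrix `R` whose rows are
#' drugs and columns diseases, with `R[i, j] = 1` when drug `i` is known to
#' treat disease `j`. Row `i` is the drug's association profile
#' \eqn{s_i^{drug}}; column `j` is the disease profile \eqn{s_j^{disease}}.
#' Unobserved pairs are 0; no distinction is made between "unverified" and
#' "verified absent" (implicit-feedback convention).
#'
#' @param values numeric matrix of 0/1, drugs in rows, diseases in columns.
#' @param drug_ids,disease_ids character vectors of unique identifiers whose
#'   lengths match the matrix dimensions.
#' @return an object of class `association_matrix` with fields `values`,
#'   `drug_ids`, `disease_ids`.
#' @export
association_matrix <- function(values, drug_ids, disease_ids) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) {
    amn_stop("association values must be 0 or 1", "value_error")
  }
  if (nrow(values) != length(drug_ids) || ncol(values) != length(disease_ids)) {
    amn_stop("id lengths do not match matrix dimensions", "shape_error")
  }
  check_ids(drug_ids, "drug_ids")
  check_ids(disease_ids, "disease_ids")
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  structure(
    list(values = values, drug_ids = as.character(drug_ids),
         disease_ids = as.character(disease_ids)),
    class = "association_matrix"
  )
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %d drugs x %d diseases, %d associations\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Symmetric similarity matrix for drugs or diseases
#'
#' Side information consumed by the denoising autoencoders: a symmetric
#' matrix of pairwise similarities in \[0,1\] with unit diagonal (e.g. 2D
#' Tanimoto similarity of chemical fingerprints for drugs, text-mined
#' phenotype similarity for diseases). How the similarities were derived is
#' upstream of this package; they are treated as opaque inputs.
#'
#' @param values square numeric matrix, symmetric within 1e-8, entries in
#'   \[0,1\], diagonal 1.
#' @param ids character identifiers, one per row/column.
#' @param axis `"drug"` or `"disease"`.
#' @return an object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, ids, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    amn_stop("similarity matrix must be square", "shape_error")
  }
  if (nrow(values) != length(ids)) {
    amn_stop("id length does not match matrix dimension", "shape_error")
  }
  check_ids(ids, paste0(axis, " ids"))
  if (length(values) > 0) {
    if (max(abs(values - t(values))) > 1e-8) {
      amn_stop("similarity matrix is not symmetric", "symmetry_error")
    }
    if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
      amn_stop("similarity entries must lie in [0,1]", "range_error")
    }
    if (max(abs(diag(values) - 1)) > 1e-8) {
      amn_stop("similarity diagonal must equal 1", "value_error")
    }
  }
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  structure(list(values = values, ids = as.character(ids), axis = axis),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> axis=%s, %d x %d\n",
              x$axis, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Bundle an association matrix with its two similarity matrices
#'
#' @param associations an [association_matrix()].
#' @param drug_sim,disease_sim [similarity_matrix()] objects whose ids match
#'   the association matrix ids in order.
#' @return an object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(associations, drug_sim, disease_sim) {
  b <- structure(list(associations = associations, drug_sim = drug_sim,
                      disease_sim = disease_sim), class = "dataset_bundle")
  rep <- validate_dataset(b)
  if (nrow(rep) > 0) {
    amn_stop(paste0("invalid dataset bundle: ",
                    paste(rep$message, collapse = "; ")), "validation_error")
  }
  b
}

#' @export
print.dataset_bundle <- function(x, ...) {
  print(x$associations)
  invisible(x)
}

#' Read a drug-disease association matrix
#'
#' Two formats are supported. `tsv_edges`: UTF-8 lines
#' `drug_id<TAB>disease_id[<TAB>1]`, no header; ids are indexed in order of
#' first appearance and duplicate edges collapse to a single 1. `mtx`: a
#' MatrixMarket coordinate file with a sidecar `.ids` file (same path with
#' extension `.ids`) listing the drug ids on the first `m` lines and the
#' disease ids on the next `n` lines.
#'
#' @param path file path.
#' @param format `"tsv_edges"` or `"mtx"`.
#' @return an [association_matrix()].
#' @export
read_association_edges <- function(path, format = c("tsv_edges", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) amn_stop(sprintf("file not found: %s", path), "io_error")
  if (format == "tsv_edges") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      return(association_matrix(matrix(0, 0, 0), character(0), character(0)))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    drug <- character(length(parts)); dis <- character(length(parts))
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      if (length(p) < 2 || length(p) > 3 || !nzchar(p[1]) || !nzchar(p[2])) {
        amn_stop(sprintf("malformed edge row at line %d", k), "parse_error")
      }
      if (length(p) == 3 && p[3] != "1") {
        amn_stop(sprintf("third column must equal 1 at line %d", k), "value_error")
      }
      drug[k] <- p[1]; dis[k] <- p[2]
    }
    drug_ids <- unique(drug); disease_ids <- unique(dis)
    m <- matrix(0, length(drug_ids), length(disease_ids))
    m[cbind(match(drug, drug_ids), match(dis, disease_ids))] <- 1
    association_matrix(m, drug_ids, disease_ids)
  } else {
    ids_path <- sub("\\.mtx$", ".ids", path)
    if (identical(ids_path, path)) ids_path <- paste0(path, ".ids")
    if (!file.exists(ids_path)) {
      amn_stop(sprintf("sidecar id file not found: %s", ids_path), "io_error")
    }
    sm <- as.matrix(Matrix::readMM(path))
    ids <- readLines(ids_path, warn = FALSE)
    if (length(ids) != nrow(sm) + ncol(sm)) {
      amn_stop("sidecar id count does not match matrix dimensions", "validation_error")
    }
    drug_ids <- if (nrow(sm) > 0) ids[seq_len(nrow(sm))] else character(0)
    disease_ids <- if (ncol(sm) > 0) ids[nrow(sm) + seq_len(ncol(sm))] else character(0)
    if (anyDuplicated(drug_ids) || anyDuplicated(disease_ids)) {
      amn_stop("duplicate ids in sidecar file", "validation_error")
    }
    if (any(sm < 0)) amn_stop("negative entries in association mtx", "value_error")
    sm[sm > 0] <- 1
    association_matrix(sm, drug_ids, disease_ids)
  }
}

#' Read a similarity matrix from CSV
#'
#' Expects a header row of ids and a first column of ids (identical, in
#' order). Asymmetry up to 1e-6 (floating-point drift in dumped symmetric
#' matrices) is silently repaired by averaging with the transpose; anything
#' larger is an error.
#'
#' @inheritParams similarity_matrix
#' @param path CSV file path.
#' @return a [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  if (!file.exists(path)) amn_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  row_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  col_ids <- colnames(vals)
  if (nrow(vals) != ncol(vals)) {
    amn_stop("similarity CSV is not square", "shape_error")
  }
  if (!identical(row_ids, col_ids)) {
    amn_stop("row ids and column ids differ in similarity CSV", "validation_error")
  }
  storage.mode(vals) <- "double"
  if (length(vals) > 0) {
    if (min(vals) < -1e-9 || max(vals) > 1 + 1e-9) {
      amn_stop("similarity entry outside [0,1]", "range_error")
    }
    vals <- pmin(pmax(vals, 0), 1)
    asym <- max(abs(vals - t(vals)))
    if (asym > 1e-6) {
      amn_stop(sprintf("similarity matrix asymmetry %.3g exceeds 1e-6", asym),
               "symmetry_error")
    }
    vals <- (vals + t(vals)) / 2
  }
  similarity_matrix(vals, row_ids, axis)
}

#' Write an association matrix
#'
#' `tsv_edges` writes one `drug<TAB>disease<TAB>1` line per association in
#' row-major order. An edge list carries ids only on its edges, so drugs or
#' diseases without any association are dropped and the reader re-indexes
#' ids by first appearance: the TSV round trip preserves the edge set
#' exactly but not necessarily the id ordering. `mtx` (MatrixMarket plus
#' `.ids` sidecar) round-trips arbitrary matrices bit-exactly and is the
#' format the CLI uses for generated datasets and model archives.
#'
#' @param a an [association_matrix()].
#' @param path output path.
#' @param format `"tsv_edges"` or `"mtx"`.
#' @export
write_association_matrix <- function(a, path, format = c("tsv_edges", "mtx")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    amn_stop(sprintf("directory does not exist: %s", dirname(path)), "io_error")
  }
  if (format == "tsv_edges") {
    idx <- which(t(a$values) == 1)  # row-major order over (drug, disease)
    if (length(idx) == 0) {
      writeLines(character(0), path)
      return(invisible(NULL))
    }
    n <- ncol(a$values)
    drug <- a$drug_ids[(idx - 1) %/% n + 1]
    dis <- a$disease_ids[(idx - 1) %% n + 1]
    writeLines(paste(drug, dis, "1", sep = "\t"), path)
  } else {
    ids_path <- sub("\\.mtx$", ".ids", path)
    if (identical(ids_path, path)) ids_path <- paste0(path, ".ids")
    Matrix::writeMM(methods::as(Matrix::Matrix(a$values, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(c(a$drug_ids, a$disease_ids), ids_path)
  }
  invisible(NULL)
}

#' Write a similarity matrix as CSV
#'
#' Values are printed with 12 significant digits, which re-reads within
#' 5e-13 of the in-memory values and is idempotent (a second write/read
#' reproduces the file bit for bit).
#'
#' @param s a [similarity_matrix()].
#' @param path output CSV path.
#' @export
write_similarity_matrix <- function(s, path) {
  if (!dir.exists(dirname(path))) {
    amn_stop(sprintf("directory does not exist: %s", dirname(path)), "io_error")
  }
  header <- paste(c("", s$ids), collapse = ",")
  if (length(s$ids) == 0) {
    writeLines(header, path)
    return(invisible(NULL))
  }
  body <- vapply(seq_along(s$ids), function(i) {
    paste(c(s$ids[i], formatC(s$values[i, ], digits = 12, format = "g")),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(NULL)
}

#' Fraction of observed associations
#'
#' The density of the association matrix: number of known drug-disease pairs
#' divided by the number of possible pairs. Published repositioning datasets
#' are extremely sparse (around 1%), which is what motivates similarity side
#' information and negative sampling.
#'
#' @param a an [association_matrix()].
#' @return a real in \[0,1\].
#' @export
sparsity <- function(a) {
  m <- nrow(a$values); n <- ncol(a$values)
  if (m == 0 || n == 0) {
    amn_stop("sparsity is undefined for an empty matrix", "value_error")
  }
  sum(a$values) / (m * n)
}

#' Validate a dataset bundle
#'
#' Checks every structural invariant (binary associations, unique ids,
#' symmetry/range/diagonal of the similarity matrices, id alignment between
#' components) and reports violations as rows of a data frame instead of
#' raising errors. An empty report means the bundle is valid.
#'
#' @param d a `dataset_bundle` (or plain list with the same fields).
#' @return data.frame with columns `component`, `check`, `message`.
#' @export
validate_dataset <- function(d) {
  rep <- list()
  add <- function(component, check, message) {
    rep[[length(rep) + 1]] <<- data.frame(component = component, check = check,
                                          message = message,
                                          stringsAsFactors = FALSE)
  }
  a <- d$associations
  if (!all(a$values %in% c(0, 1))) {
    add("associations", "binary", "association cells must all be 0 or 1")
  }
  if (anyDuplicated(a$drug_ids)) {
    add("associations", "duplicate_ids", "duplicate drug ids")
  }
  if (anyDuplicated(a$disease_ids)) {
    add("associations", "duplicate_ids", "duplicate disease ids")
  }
  check_sim <- function(s, name, expect_ids) {
    v <- s$values
    if (nrow(v) != ncol(v)) {
      add(name, "shape", sprintf("%s is not square", name))
      return(invisible(NULL))
    }
    if (length(v) > 0) {
      if (max(abs(v - t(v))) > 1e-8) {
        add(name, "symmetry", sprintf("%s is not symmetric within 1e-8", name))
      }
      if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
        add(name, "range", sprintf("%s has entries outside [0,1]", name))
      }
      if (max(abs(diag(v) - 1)) > 1e-8) {
        add(name, "diagonal", sprintf("%s diagonal differs from 1", name))
      }
    }
    if (anyDuplicated(s$ids)) add(name, "duplicate_ids", sprintf("duplicate ids in %s", name))
    if (!identical(s$ids, expect_ids)) {
      add(name, "id_mismatch",
          sprintf("%s ids do not match association %s ids", name, s$axis))
    }
  }
  check_sim(d$drug_sim, "drug_sim", a$drug_ids)
  check_sim(d$disease_sim, "disease_sim", a$disease_ids)
  if (length(rep) == 0) {
    data.frame(component = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rep)
  }
}
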