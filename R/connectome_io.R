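#' @useDynLib rmfm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd rnorm runif rbinom setNames pt pf qt quantile
#' @importFrom utils read.delim write.table head
NULL

# ---- Parcellation ----------------------------------------------------------

#' Construct a cortical parcellation table
#'
#' A parcellation assigns every cortical parcel an id, a hemisphere, an
#' intrinsic-network label, and (optionally) the id of its contralateral
#' homologue. Region ids are 0-based and contiguous; homologue pairing must be
#' symmetric so that hemisphere flipping is an involution.
#'
#' @param region_id integer vector, 0..N-1 without gaps.
#' @param name character vector of parcel names.
#' @param hemisphere character vector, each "left" or "right".
#' @param network character vector of intrinsic-network labels.
#' @param homologue_id integer vector of contralateral region ids, or NA where
#'   a parcel has no homologue.
#' @return An object of class `parcellation` (a data.frame).
#' @export
parcellation <- function(region_id, name, hemisphere, network,
                         homologue_id = NA_integer_) {
  df <- data.frame(
    region_id = as.integer(region_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    network = as.character(network),
    homologue_id = suppressWarnings(as.integer(homologue_id)),
    stringsAsFactors = FALSE
  )
  validate_parcellation(df)
  class(df) <- c("parcellation", "data.frame")
  df
}

validate_parcellation <- function(df) {
  n <- nrow(df)
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region_id in parcellation", call. = FALSE)
  }
  if (!identical(sort(df$region_id), 0:(n - 1L))) {
    stop("region_ids must be 0..N-1 with no gaps", call. = FALSE)
  }
  if (!all(df$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  if (anyNA(df$network) || any(!nzchar(df$network))) {
    stop("every region needs exactly one network label", call. = FALSE)
  }
  hid <- df$homologue_id
  has <- !is.na(hid)
  if (any(has)) {
    if (any(hid[has] < 0 | hid[has] >= n)) {
      stop("homologue_id out of range", call. = FALSE)
    }
    # pairing must be symmetric: homologue(homologue(i)) == i
    back <- hid[match(hid[has], df$region_id)]
    if (anyNA(back) || any(back != df$region_id[has])) {
      stop("homologue pairing is not symmetric", call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a parcellation from a tab-separated file
#'
#' Expects a header line with columns `region_id`, `name`, `hemisphere`,
#' `network`, `homologue_id` (NA allowed for missing homologues).
#'
#' @param path file path.
#' @return A validated [parcellation].
#' @export
read_parcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "hemisphere", "network", "homologue_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parcellation file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parcellation(df$region_id, df$name, df$hemisphere, df$network,
               df$homologue_id)
}

#' Write a parcellation to a tab-separated file
#' @param parc a [parcellation].
#' @param path output path.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- Connectome matrices ---------------------------------------------------

new_structural_connectome <- function(weights, parc, degenerate = FALSE) {
  structure(list(weights = weights, parcellation = parc,
                 degenerate = degenerate),
            class = "structural_connectome")
}

new_functional_connectome <- function(values, parc, space = "r") {
  structure(list(values = values, parcellation = parc, space = space),
            class = "functional_connectome")
}

#' Construct a structural connectome
#'
#' @param weights N x N symmetric non-negative matrix with zero diagonal
#'   (streamline-count-like units).
#' @param parc matching [parcellation].
#' @return `structural_connectome` object.
#' @export
structural_connectome <- function(weights, parc) {
  weights <- as.matrix(weights)
  validate_square(weights, parc)
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("structural connectome must be symmetric", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative structural weight", call. = FALSE)
  diag(weights) <- 0
  new_structural_connectome(weights, parc)
}

#' Construct a functional connectome
#'
#' @param values N x N symmetric correlation (space = "r") or Fisher-z
#'   (space = "z") matrix.
#' @param parc matching [parcellation].
#' @param space "r" or "z".
#' @return `functional_connectome` object.
#' @export
functional_connectome <- function(values, parc, space = c("r", "z")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  validate_square(values, parc)
  if (max(abs(values - t(values))) > 1e-8) {
    stop("functional connectome must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (space == "r") {
    off <- values[upper.tri(values)]
    if (any(off < -1 - 1e-12 | off > 1 + 1e-12)) {
      stop("correlation entries outside [-1, 1]", call. = FALSE)
    }
    diag(values) <- 1
  }
  new_functional_connectome(values, parc, space)
}

validate_square <- function(m, parc) {
  n <- nrow(parc)
  if (nrow(m) != n || ncol(m) != n) {
    stop(sprintf("matrix is %dx%d but parcellation has %d regions",
                 nrow(m), ncol(m), n), call. = FALSE)
  }
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite matrix entry", call. = FALSE)
  invisible(m)
}

#' Read a connectome matrix from a tab-separated file
#'
#' The file is a square numeric block (no header). Mild asymmetries (at most
#' 1e-8 in absolute value) are repaired by averaging with the transpose;
#' larger ones are rejected.
#'
#' @param path file path.
#' @param parc matching [parcellation].
#' @param kind "sc" for structural or "fc" for functional.
#' @param space for kind = "fc": "r" (correlations) or "z" (Fisher-z).
#' @return `structural_connectome` or `functional_connectome`.
#' @export
read_matrix <- function(path, parc, kind = c("sc", "fc"), space = "r") {
  kind <- match.arg(kind)
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  validate_square(m, parc)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    stop(sprintf("matrix asymmetry %.3g exceeds 1e-8", asym), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (kind == "sc") structural_connectome(m, parc)
  else functional_connectome(m, parc, space)
}

#' Write a connectome matrix to a tab-separated file
#' @param x `structural_connectome` or `functional_connectome`.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "structural_connectome")) x$weights else x$values
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalise a structural connectome to unit maximum weight
#'
#' Divides all weights by the global maximum so the strongest connection has
#' weight 1; this puts the global coupling G on a comparable scale across
#' connectomes. An all-zero connectome passes through unchanged with its
#' `degenerate` flag set.
#'
#' @param sc a `structural_connectome`.
#' @return Normalised `structural_connectome` (idempotent).
#' @export
normalize_sc <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  mx <- max(sc$weights)
  if (mx == 0) {
    warning("all-zero structural connectome; normalisation skipped")
    return(new_structural_connectome(sc$weights, sc$parcellation,
                                     degenerate = TRUE))
  }
  new_structural_connectome(sc$weights / mx, sc$parcellation)
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("structural_connectome: %d regions, max weight %.4g, density %.2f\n",
              nrow(x$weights), max(x$weights),
              mean(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' @export
print.functional_connectome <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("functional_connectome (%s-space): %d regions, mean off-diagonal %.3f\n",
              x$space, nrow(x$values), mean(off)))
  invisible(x)
}
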