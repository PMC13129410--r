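# Phylogenetic correlation structure: Newick input, Grafen branch lengths,
# and the species-by-species correlation matrix used as a random-effect
# covariance. Tree handling is delegated to ape.

#' Read and validate a phylogeny
#'
#' Reads a Newick tree from a file path or a literal string. Polytomies
#' (including a basal polytomy, read as a rooted star) are allowed; existing
#' branch lengths are retained. Duplicate tip labels are an error, since
#' species matching requires unique tips.
#'
#' @param x File path or Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(x) {
  tree <- if (length(x) == 1 && !grepl("(", x, fixed = TRUE) && file.exists(x)) {
    ape::read.tree(file = x)
  } else {
    tryCatch(ape::read.tree(text = x),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)),
             warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  }
  if (is.null(tree)) stop("Newick parse error: no tree found")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  # Newick input is rooted at its outermost grouping; a basal polytomy is
  # treated as a rooted star, so no is.rooted() check here
  tree
}

#' Grafen branch lengths
#'
#' Assigns each internal node the height (number of descendant tips - 1)
#' raised to `power`, rescaled so the root has height 1 and tips height 0;
#' branch lengths are parent minus child heights, giving an ultrametric tree.
#' Polytomies are handled natively (heights depend only on tip counts).
#'
#' @param tree A rooted `phylo` object.
#' @param power Exponent applied to node heights before rescaling.
#' @return The tree with Grafen branch lengths.
#' @export
grafen_lengths <- function(tree, power = 1) {
  stopifnot(inherits(tree, "phylo"), power > 0)
  if (length(tree$tip.label) < 2) stop("no branches: tree has a single tip")
  ape::compute.brlen(tree, method = "Grafen", power = power)
}

#' Normalize species labels for matching
#'
#' Case-insensitive with spaces and underscores treated as equivalent, so
#' "Passer domesticus" matches "passer_domesticus".
#'
#' @param x Character vector of species names.
#' @export
normalize_species <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(x)))
}

#' Phylogenetic correlation matrix from a tree
#'
#' Entry (i, j) is the shared root-to-MRCA depth of tips i and j divided by
#' total tip depth; the diagonal is exactly 1. The tree should be ultrametric
#' (e.g., after [grafen_lengths()]); otherwise a warning is issued and each
#' pair is normalized by its tip depths (correlation rescaling). Trees
#' without branch lengths get Grafen lengths first.
#'
#' @param tree A rooted `phylo` object.
#' @param species Optional vector of species names the matrix must cover (and
#'   is reordered to, after label normalization); missing species are an
#'   error, never silently dropped.
#' @param jitter Nonnegative ridge added to the diagonal (then rescaled back
#'   to unit diagonal) for near-singular matrices; default 0.
#' @return Symmetric PSD correlation matrix with species as dimnames.
#' @export
phylo_correlation <- function(tree, species = NULL, jitter = 0) {
  stopifnot(inherits(tree, "phylo"), jitter >= 0)
  if (is.null(tree$edge.length)) tree <- grafen_lengths(tree)
  if (!ape::is.ultrametric(tree, tol = 1e-8)) {
    warning("tree is not ultrametric; normalizing shared depths by tip depths")
  }
  A <- ape::vcv(tree, corr = TRUE)
  if (jitter > 0) {
    A <- A + diag(jitter, nrow(A))
    A <- stats::cov2cor(A)
  }
  if (!is.null(species)) {
    want <- unique(as.character(species))
    key <- normalize_species(rownames(A))
    idx <- match(normalize_species(want), key)
    if (anyNA(idx)) {
      stop("species missing from tree: ",
           paste(want[is.na(idx)], collapse = ", "))
    }
    A <- A[idx, idx, drop = FALSE]
    dimnames(A) <- list(want, want)
  }
  A <- (A + t(A)) / 2
  diag(A) <- 1
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) stop("phylogenetic correlation matrix is not PSD")
  A
}

#' Write a phylogenetic correlation matrix as CSV
#'
#' @param A Correlation matrix with species dimnames.
#' @param path Output file.
#' @export
write_correlation_csv <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
}
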