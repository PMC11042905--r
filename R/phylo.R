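# Species-tree utilities: parsing, distance ordering relative to the
# reference species, and total-evolutionary-distance budgets of species
# subsets under branch-length-preserving pruning. Branch lengths are in
# substitutions per site throughout.

#' Parse a Newick species tree
#'
#' Parses Newick text (or a file) into an `ape::phylo` tree, validating the
#' properties the rest of the package relies on: unique leaf names and a
#' finite non-negative branch length on every edge (path distances would
#' otherwise be undefined).
#'
#' @param text Newick text, or the path to a file containing it.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,C:3);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- if (file.exists(text) && !grepl(";", text, fixed = TRUE)) {
    ape::read.tree(file = text)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tree)) rlang::abort("could not parse Newick input")
  validate_phylogeny(tree)
}

#' @rdname parse_newick
#' @param tree A `phylo` object to validate.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) rlang::abort("`tree` must be a `phylo` object")
  if (anyDuplicated(tree$tip.label)) {
    rlang::abort(sprintf("duplicate leaf name(s): %s",
                         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  bl <- tree$edge.length
  if (is.null(bl) || length(bl) != nrow(tree$edge) || anyNA(bl) || any(!is.finite(bl))) {
    rlang::abort("every edge must carry a finite branch length")
  }
  if (any(bl < 0)) rlang::abort("branch lengths must be non-negative")
  tree
}

#' @rdname parse_newick
#' @param path Output path for `write_newick`.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Order species by evolutionary distance from a reference species
#'
#' Computes, for every other leaf, the sum of branch lengths on the unique
#' path from the reference leaf, and returns the species sorted by ascending
#' distance (ties broken lexicographically by species name). This ordering
#' drives the species sweep: augment with the closest species first, then
#' the two closest, and so on.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param reference Name of the reference leaf (the species the training
#'   sequences come from); excluded from the output.
#' @return A tibble `(species, distance)` sorted ascending.
#' @examples
#' distances_from(parse_newick("((A:1,B:2):1,C:3);"), "A")
#' @export
distances_from <- function(tree, reference) {
  validate_phylogeny(tree)
  if (!reference %in% tree$tip.label) {
    rlang::abort(sprintf("reference species '%s' is not a leaf of the tree", reference))
  }
  d <- ape::cophenetic.phylo(tree)[reference, ]
  out <- tibble::tibble(species = names(d), distance = unname(d))
  out <- dplyr::filter(out, .data$species != reference)
  dplyr::arrange(out, .data$distance, .data$species)
}

#' Total evolutionary distance of a species subset
#'
#' Prunes the tree to the minimal subtree spanning `keep`, collapsing unary
#' internal nodes by adding their incident branch lengths (the
#' branch-length-preserving pruning convention), and returns the sum of all
#' remaining branch lengths. This is the "total evolutionary distance"
#' budget of a species subset; it is monotone non-decreasing as `keep`
#' grows.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param keep Nonempty character vector of leaf names to retain.
#' @return A single number: the branch-length sum of the pruned tree
#'   (0 when `keep` has a single species).
#' @examples
#' total_distance(parse_newick("((A:1,B:2):1,C:3);"), c("A", "C")) # 5
#' @export
total_distance <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(keep) == 0L) rlang::abort("`keep` must be nonempty")
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown species in `keep`: %s", paste(unknown, collapse = ", ")))
  }
  if (length(keep) == 1L) return(0)
  pruned <- ape::keep.tip(tree, keep)
  sum(pruned$edge.length)
}

#' Species-sweep schedule
#'
#' Builds the schedule of nested species subsets used by the species sweep:
#' species enter in ascending distance from the reference, and each row
#' reports the cumulative total evolutionary distance of the subset pruned
#' from the full tree (the reference leaf itself is kept in every subset).
#'
#' @inheritParams distances_from
#' @param n_max Optional cap on the number of species included.
#' @return A tibble `(n_species, species_added, distance_from_reference,
#'   cumulative_total_distance)` with one row per sweep step.
#' @export
species_sweep_table <- function(tree, reference, n_max = Inf) {
  ord <- distances_from(tree, reference)
  n <- min(nrow(ord), n_max)
  ord <- ord[seq_len(n), ]
  cum <- purrr::map_dbl(seq_len(n), function(i) {
    total_distance(tree, c(reference, ord$species[seq_len(i)]))
  })
  tibble::tibble(n_species = seq_len(n),
                 species_added = ord$species,
                 distance_from_reference = ord$distance,
                 cumulative_total_distance = cum)
}
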