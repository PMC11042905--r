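# Homolog archives: for each reference training sequence, the set of
# homologous sequences available in other species, stored pre-resized to the
# dataset input length. Internally a tibble (ref_id, species, seq) carrying
# the dataset length and the full reference id universe as attributes, so
# reference sequences with zero homologs stay representable.

new_homolog_archive <- function(tbl, target_len, ref_ids) {
  out <- tibble::as_tibble(tbl[c("ref_id", "species", "seq")])
  attr(out, "target_len") <- as.integer(target_len)
  attr(out, "ref_ids") <- ref_ids
  class(out) <- c("homolog_archive", class(tibble::tibble()))
  out
}

#' Build a homolog archive from raw per-species homolog calls
#'
#' Collapses raw homolog records (as produced upstream by whole-genome
#' alignment extraction, or by [evolve_homologs()]) into one sequence per
#' (reference id, species) pair, resizes every kept sequence to the dataset
#' input length about its midpoint, and optionally drops sequences that
#' contain `N`.
#'
#' When several homologs are found for the same reference sequence in the
#' same species, the first one in input order is kept; the archive is
#' therefore deterministic given input order.
#'
#' @param raw A data frame with columns `ref_id`, `species`, `seq`.
#' @param target_len Dataset input length; every stored homolog is resized
#'   to this length via [resize_from_midpoint()].
#' @param ref_ids Character vector of all valid reference ids (typically the
#'   training ids). Raw entries with unknown `ref_id` are an error; ids with
#'   no homolog remain in the archive with an empty set.
#' @param drop_n If `TRUE`, kept homologs still containing `N` after
#'   resizing are excluded.
#' @return A `homolog_archive`: a tibble `(ref_id, species, seq)` with the
#'   dataset length and reference id universe attached.
#' @examples
#' raw <- tibble::tibble(ref_id = "s1", species = c("spA", "spA"),
#'                       seq = c("ACGTACGT", "TTTTTTTT"))
#' arc <- build_archive(raw, target_len = 8, ref_ids = c("s1", "s2"))
#' nrow(arc) # 1: first spA match kept, s2 present with an empty set
#' @export
build_archive <- function(raw, target_len, ref_ids = NULL, drop_n = FALSE) {
  stopifnot(is.data.frame(raw))
  if (nrow(raw) == 0L) {
    return(new_homolog_archive(
      tibble::tibble(ref_id = character(), species = character(), seq = character()),
      target_len, ref_ids %||% character()))
  }
  if (!all(c("ref_id", "species", "seq") %in% names(raw))) {
    rlang::abort("`raw` must have columns ref_id, species, seq")
  }
  if (is.null(ref_ids)) {
    ref_ids <- unique(raw$ref_id)
  } else {
    unknown <- setdiff(unique(raw$ref_id), ref_ids)
    if (length(unknown) > 0L) {
      rlang::abort(sprintf("raw homologs refer to unknown reference id(s): %s",
                           paste(unknown, collapse = ", ")))
    }
  }
  kept <- dplyr::distinct(tibble::as_tibble(raw), .data$ref_id, .data$species,
                          .keep_all = TRUE)
  kept$seq <- resize_from_midpoint(kept$seq, target_len)
  if (drop_n) kept <- dplyr::filter(kept, !stringr::str_detect(.data$seq, "N"))
  new_homolog_archive(kept, target_len, ref_ids)
}

#' @rdname build_archive
#' @param x An object to test.
#' @export
is_homolog_archive <- function(x) inherits(x, "homolog_archive")

archive_target_len <- function(archive) attr(archive, "target_len")
archive_ref_ids <- function(archive) attr(archive, "ref_ids")

#' Restrict an archive to a set of species
#'
#' Keeps only homologs whose species is in `species`. Reference ids whose
#' homolog set becomes empty remain part of the archive (batch generation
#' falls back to the reference sequence for them), so restricting species
#' never changes which sequences can be trained on.
#'
#' @param archive A `homolog_archive`.
#' @param species Nonempty character vector of species to keep. Names
#'   matching no homolog in the archive trigger a warning, not an error.
#' @return A `homolog_archive` with the same reference id universe.
#' @export
subset_species <- function(archive, species) {
  stopifnot(is_homolog_archive(archive))
  if (length(species) == 0L) rlang::abort("`species` must be nonempty")
  missing <- setdiff(species, unique(archive$species))
  if (length(missing) > 0L) {
    rlang::warn(sprintf("species with no homologs in archive: %s",
                        paste(missing, collapse = ", ")))
  }
  new_homolog_archive(dplyr::filter(archive, .data$species %in% !!species),
                      archive_target_len(archive), archive_ref_ids(archive))
}

#' Summarise an archive
#'
#' @param archive A `homolog_archive`.
#' @return A list with `target_len`, `n_ref` (size of the reference id
#'   universe), `total` homolog count, and a tibble `species` of per-species
#'   counts.
#' @export
homolog_manifest <- function(archive) {
  stopifnot(is_homolog_archive(archive))
  per_species <- dplyr::count(tibble::as_tibble(archive), .data$species, name = "n")
  list(target_len = archive_target_len(archive),
       n_ref = length(archive_ref_ids(archive)),
       total = nrow(archive),
       species = dplyr::arrange(per_species, .data$species))
}

#' Per-reference homolog counts
#'
#' @param archive A `homolog_archive`.
#' @return A tibble `(ref_id, n)` covering every id in the reference
#'   universe, including those with zero homologs.
#' @export
homolog_counts <- function(archive) {
  stopifnot(is_homolog_archive(archive))
  counts <- dplyr::count(tibble::as_tibble(archive), .data$ref_id, name = "n")
  all_ids <- tibble::tibble(ref_id = archive_ref_ids(archive))
  out <- dplyr::left_join(all_ids, counts, by = "ref_id")
  out$n[is.na(out$n)] <- 0L
  out
}

#' Serialise / load a homolog archive
#'
#' The on-disk form is a multi-FASTA with `ref_id|species` headers plus a
#' JSON manifest holding the dataset length, the reference id universe, and
#' per-species counts (rechecked on load).
#'
#' @param archive A `homolog_archive`.
#' @param fasta_path,manifest_path Output/input paths.
#' @return `write_archive` returns `fasta_path` invisibly; `read_archive`
#'   returns a `homolog_archive`.
#' @export
write_archive <- function(archive, fasta_path, manifest_path) {
  stopifnot(is_homolog_archive(archive))
  man <- homolog_manifest(archive)
  write_fasta(tibble::tibble(id = archive$ref_id, species = archive$species,
                             seq = archive$seq), fasta_path)
  jsonlite::write_json(
    list(target_len = man$target_len, total = man$total,
         ref_ids = archive_ref_ids(archive),
         species = man$species),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}

#' @rdname write_archive
#' @export
read_archive <- function(fasta_path, manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  fa <- Biostrings::readDNAStringSet(fasta_path)
  parts <- stringr::str_split_fixed(names(fa), stringr::fixed("|"), 2L)
  arc <- new_homolog_archive(
    tibble::tibble(ref_id = parts[, 1L], species = parts[, 2L],
                   seq = unname(toupper(as.character(fa)))),
    man$target_len, man$ref_ids)
  got <- homolog_manifest(arc)
  want <- tibble::as_tibble(man$species)
  if (!isTRUE(all.equal(got$species$n[order(got$species$species)],
                        as.integer(want$n[order(want$species)])))) {
    rlang::abort("archive manifest counts do not match sequences on disk")
  }
  arc
}

# Fast lookup structure used by the batch generator: list keyed by ref_id of
# tibbles (species, seq). Built once per training call.
archive_index <- function(archive) {
  tbl <- tibble::as_tibble(archive)
  idx <- split(tbl[c("species", "seq")], factor(tbl$ref_id, levels = archive_ref_ids(archive)))
  idx
}
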