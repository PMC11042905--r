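# Readers/writers for the package's on-disk formats: multi-FASTA with
# structured headers, BED6 intervals, and the tab-separated label table.

.header_interval_re <- "^(.+):([0-9]+)-([0-9]+)\\(([+-])\\)$"

.parse_fasta_headers <- function(headers) {
  # grammar: "id|species|chrom:start-end(strand)"; fields after id optional
  ids <- character(length(headers))
  species <- rep(NA_character_, length(headers))
  chrom <- rep(NA_character_, length(headers))
  start <- rep(NA_integer_, length(headers))
  end <- rep(NA_integer_, length(headers))
  strand <- rep(NA_character_, length(headers))
  for (i in seq_along(headers)) {
    h <- strsplit(headers[i], " ", fixed = TRUE)[[1L]][1L]
    parts <- strsplit(h, "|", fixed = TRUE)[[1L]]
    ids[i] <- parts[1L]
    if (length(parts) >= 2L && nzchar(parts[2L])) species[i] <- parts[2L]
    if (length(parts) >= 3L) {
      m <- regmatches(parts[3L], regexec(.header_interval_re, parts[3L]))[[1L]]
      if (length(m) == 5L) {
        chrom[i] <- m[2L]
        start[i] <- as.integer(m[3L])
        end[i] <- as.integer(m[4L])
        strand[i] <- m[5L]
      } else {
        rlang::warn(sprintf(
          "malformed interval field '%s' in header '%s'; keeping id only", parts[3L], h))
        species[i] <- NA_character_
      }
    }
    if (length(parts) > 3L) {
      rlang::warn(sprintf("header '%s' has extra fields; keeping id/species/interval only", h))
    }
  }
  tibble::tibble(id = ids, species = species, chrom = chrom,
                 start = start, end = end, strand = strand)
}

#' Read a multi-FASTA file of fixed-role DNA sequences
#'
#' Reads a (possibly gzipped) multi-FASTA file whose headers follow the
#' grammar `id|species|chrom:start-end(strand)`, with every field after the
#' id optional. Coordinates are 0-based half-open (BED convention).
#' Sequences are uppercased; soft-masking is not retained.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `species`, `chrom`, `start`,
#'   `end`, `strand` (missing header fields are `NA`), in file order.
#' @details Duplicate ids within one file are an error. A malformed interval
#'   field falls back to an id-only record with a warning. When an interval
#'   is present, `end - start` must equal the sequence length.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  meta <- .parse_fasta_headers(names(ss))
  if (anyDuplicated(meta$id)) {
    rlang::abort(sprintf(
      "duplicate sequence id(s) in '%s': %s", path,
      paste(unique(meta$id[duplicated(meta$id)]), collapse = ", ")))
  }
  seqs <- .check_dna(as.character(ss))
  bad <- !is.na(meta$start) & (meta$end - meta$start) != nchar(seqs)
  if (any(bad)) {
    rlang::abort(sprintf(
      "interval width does not match sequence length for id(s): %s",
      paste(meta$id[bad], collapse = ", ")))
  }
  dplyr::mutate(meta, seq = unname(seqs), .after = "id")
}

#' Write sequence records to a multi-FASTA file
#'
#' Inverse of [read_fasta()]: headers are rebuilt from the non-missing
#' columns using the `id|species|chrom:start-end(strand)` grammar and
#' sequence lines are wrapped at 80 columns.
#'
#' @param records A data frame with at least `id` and `seq`; optional
#'   `species`, `chrom`, `start`, `end`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  n <- nrow(records)
  species <- if ("species" %in% names(records)) records$species else rep(NA_character_, n)
  headers <- records$id
  has_iv <- if (all(c("chrom", "start", "end", "strand") %in% names(records))) {
    !is.na(records$chrom) & !is.na(records$start)
  } else rep(FALSE, n)
  iv <- character(n)
  if (any(has_iv)) {
    iv[has_iv] <- sprintf("%s:%d-%d(%s)", records$chrom[has_iv],
                          records$start[has_iv], records$end[has_iv],
                          records$strand[has_iv])
  }
  has_sp <- !is.na(species)
  headers <- ifelse(has_iv,
                    paste(records$id, ifelse(has_sp, species, ""), iv, sep = "|"),
                    ifelse(has_sp, paste(records$id, species, sep = "|"), records$id))
  ss <- Biostrings::DNAStringSet(.check_dna(records$seq))
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read and validate a label table
#'
#' Reads the tab-separated label table associating each training sequence
#' with one or more task values (real-valued regression targets or 0/1
#' class labels) and a chromosome used for split assignment. Expected
#' header: `id<TAB>chrom<TAB>task1[<TAB>task2...]`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id`, `chrom`, and one numeric column per
#'   task, validated for unique ids and no missing task values.
#' @export
read_label_table <- function(path) {
  labels <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              id = readr::col_character(),
                              chrom = readr::col_character(),
                              .default = readr::col_double()))
  validate_label_table(labels)
}

#' @rdname read_label_table
#' @param labels A data frame to validate in place of reading from disk.
#' @export
validate_label_table <- function(labels) {
  if (!all(c("id", "chrom") %in% names(labels))) {
    rlang::abort("label table must have `id` and `chrom` columns")
  }
  tasks <- label_tasks(labels)
  if (length(tasks) == 0L) rlang::abort("label table declares no tasks")
  if (anyDuplicated(labels$id)) {
    rlang::abort(sprintf("duplicate id(s) in label table: %s",
                         paste(unique(labels$id[duplicated(labels$id)]), collapse = ", ")))
  }
  if (anyNA(labels[tasks])) rlang::abort("label table has missing task values")
  tibble::as_tibble(labels)
}

#' @rdname read_label_table
#' @export
label_tasks <- function(labels) setdiff(names(labels), c("id", "chrom"))

#' Write a label table
#' @param labels A label table (see [read_label_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  readr::write_tsv(validate_label_table(labels), path)
  invisible(path)
}

#' Read/write BED6 intervals
#'
#' Thin wrappers around `rtracklayer` import/export presenting BED6 records
#' as a tibble with 0-based half-open coordinates, the internal convention.
#'
#' @param path Path to a BED file.
#' @return For `read_bed`, a tibble with columns `chrom`, `start`, `end`,
#'   `id`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  rlang::check_installed("rtracklayer")
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_bed
#' @param records A data frame with `chrom`, `start`, `end` and optionally
#'   `id`, `score`, `strand` columns (0-based half-open).
#' @export
write_bed <- function(records, path) {
  rlang::check_installed("rtracklayer")
  n <- nrow(records)
  strand <- if ("strand" %in% names(records)) records$strand else rep("*", n)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = strand
  )
  gr$name <- if ("id" %in% names(records)) records$id else paste0("region", seq_len(n))
  gr$score <- if ("score" %in% names(records)) records$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
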