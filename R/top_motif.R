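#' Dominant TSS from a CAGE 5'-end profile
#'
#' The transcription start site is the genomic position carrying the most
#' CAGE 5'-end reads; ties are broken toward the 5'-most position (the
#' smallest coordinate on the plus strand, the largest on the minus strand),
#' which favors the longest 5'UTR and is conservative for TOP detection.
#'
#' @param profile Tibble with columns `transcript_id`, `strand` (`"+"`/`"-"`),
#'   `pos` (genomic position) and `count` (5'-end reads, >= 0). May contain
#'   several transcripts.
#' @return Tibble `transcript_id`, `strand`, `tss_position`, `tss_count`,
#'   `total_count`.
#' @export
call_tss_from_cage <- function(profile) {
  need <- c("transcript_id", "strand", "pos", "count")
  if (!all(need %in% names(profile))) {
    abort("profile needs columns transcript_id, strand, pos, count.")
  }
  if (any(profile$count < 0)) abort("CAGE counts must be >= 0.")
  out <- profile |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d$count) == 0) {
        abort(paste0("all-zero CAGE profile for transcript ", key$transcript_id))
      }
      strand <- d$strand[1]
      top <- d[d$count == max(d$count), ]
      pos <- if (strand == "-") max(top$pos) else min(top$pos)
      tibble(strand = strand, tss_position = pos,
             tss_count = max(d$count), total_count = sum(d$count))
    }) |>
    dplyr::ungroup()
  out[match(unique(profile$transcript_id), out$transcript_id), ]
}

#' TOP-motif classification of a 5'-terminal sequence
#'
#' A transcript carries a 5' terminal oligopyrimidine (TOP) motif when its
#' 5' end starts with a C or U base and continues in a run of pyrimidines.
#' The initial pyrimidine run (counting the first base) must reach
#' `min_run` for a TOP call; the run length is reported regardless.
#'
#' @param five_prime_sequence Character vector of 5'->3' sequences
#'   (alphabet ACGTU, case-insensitive).
#' @param min_run Minimum initial pyrimidine run length (default 5).
#' @param transcript_id Optional ids for the output (defaults to names or
#'   index).
#' @return Tibble `transcript_id`, `five_prime_sequence`, `first_base`,
#'   `pyrimidine_run_length`, `is_top`.
#' @export
classify_top_motif <- function(five_prime_sequence, min_run = 5,
                               transcript_id = NULL) {
  if (!length(five_prime_sequence) || any(!nzchar(five_prime_sequence))) {
    abort("sequences must be non-empty.")
  }
  ids <- transcript_id %||% names(five_prime_sequence) %||%
    paste0("tx", seq_along(five_prime_sequence))
  seq_up <- toupper(five_prime_sequence)
  bad <- regexpr("[^ACGTU]", seq_up)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("invalid character '%s' at position %d of sequence %s",
                  substr(seq_up[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  norm <- chartr("U", "T", seq_up)             # T/U equivalence
  run <- attr(regexpr("^[CT]*", norm), "match.length")
  first <- substr(norm, 1, 1)
  tibble(transcript_id = ids,
         five_prime_sequence = as.character(five_prime_sequence),
         first_base = chartr("T", "U", first),
         pyrimidine_run_length = as.integer(run),
         is_top = first %in% c("C", "T") & run >= min_run)
}

#' TOP calls for a transcript annotation from CAGE profiles and sequence
#'
#' Calls the dominant TSS per transcript from strand-split CAGE 5'-end
#' profiles, extracts the 5'-terminal sequence downstream of the called TSS
#' from the genome, and applies the TOP-motif rule.
#'
#' @param profile CAGE profile tibble (see [call_tss_from_cage()]), with a
#'   `chrom` column when a genome is supplied.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences (1-based indexing into the string).
#' @param annot Tibble with `transcript_id`, `chrom` (used to locate each
#'   transcript's sequence).
#' @param utr_length Number of bases of 5' terminus examined (default 30).
#' @param min_run Minimum pyrimidine run for a TOP call.
#' @return The [classify_top_motif()] tibble joined to the TSS calls.
#' @export
call_top_annotations <- function(profile, genome, annot, utr_length = 30,
                                 min_run = 5) {
  tss <- call_tss_from_cage(profile)
  tss <- dplyr::left_join(tss, annot[, c("transcript_id", "chrom")],
                          by = "transcript_id")
  if (anyNA(tss$chrom)) abort("annotation lacks chrom for some transcripts.")
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  seqs <- vapply(seq_len(nrow(tss)), function(i) {
    chrom_seq <- genome[[tss$chrom[i]]]
    if (is.null(chrom_seq)) abort(paste0("chromosome absent from genome: ", tss$chrom[i]))
    p <- tss$tss_position[i]
    if (tss$strand[i] == "+") {
      substr(chrom_seq, p, min(p + utr_length - 1, nchar(chrom_seq)))
    } else {
      revcomp_dna(substr(chrom_seq, max(p - utr_length + 1, 1), p))
    }
  }, character(1))
  calls <- classify_top_motif(seqs, min_run = min_run,
                              transcript_id = tss$transcript_id)
  dplyr::left_join(tss, calls, by = "transcript_id")
}

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(chartr("Uu", "Tt", sequences)), path)
  invisible(path)
}
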