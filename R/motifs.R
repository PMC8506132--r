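# FASTA reading and wildcard motif scanning. Conserved loop motifs such as
# NLTXXH (the beta6-alpha10 loop signature, N at 181 and H at 186 in the
# Haloferax volcanii G6PDH numbering) and YERG are exact patterns in which
# 'X' matches any residue; hits may overlap.

amino_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from FASTA
#'
#' Parses with [seqinr::read.fasta()]; sequences are uppercased, whitespace
#' is stripped and trailing `*` terminators removed. Records with empty
#' sequences are skipped with a warning.
#'
#' @param x File path or FASTA text.
#' @return A tibble `id`, `sequence`.
#' @examples
#' read_fasta(">a\nMKV\n")
#' @export
read_fasta <- function(x) {
  lines <- pdb_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(trimws(lines[1]), ">")) {
    abort("Not FASTA: input must start with a '>' header.",
          class = "halokin_format_error")
  }
  # drop headerless/empty records up front (they derail downstream parsing)
  is_header <- startsWith(trimws(lines), ">")
  rec_id <- cumsum(is_header)
  has_seq <- vapply(seq_len(max(rec_id)), function(k) {
    any(!is_header & rec_id == k &
          nzchar(gsub("[[:space:]*]", "", lines)))
  }, logical(1))
  if (any(!has_seq)) {
    bad_ids <- sub("^>", "", trimws(lines[is_header]))[!has_seq]
    warn(sprintf("Skipping %d record(s) with empty sequence: %s",
                 sum(!has_seq), paste(bad_ids, collapse = ", ")),
         class = "halokin_empty_record")
    lines <- lines[has_seq[rec_id]]
  }
  con <- textConnection(paste(lines, collapse = "\n"))
  on.exit(close(con))
  recs <- seqinr::read.fasta(con, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE, strip.desc = TRUE)
  ids <- unname(vapply(recs, function(r) attr(r, "name"), character(1)))
  seqs <- unname(toupper(gsub("[[:space:]*]", "",
                              vapply(recs, as.character, character(1)))))
  tibble(id = ids, sequence = seqs)
}

validate_motif <- function(pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, c(amino_letters, "X"))
  if (length(bad) > 0) {
    abort(sprintf("Illegal motif character(s): %s (one-letter codes plus 'X' allowed).",
                  paste(unique(bad), collapse = ", ")),
          class = "halokin_invalid_parameter")
  }
  pattern
}

#' Scan a sequence for a wildcard motif
#'
#' Reports every (possibly overlapping) occurrence of an exact amino-acid
#' pattern in which `X` matches any residue. Matching is case-insensitive
#' and positions are 1-based, matching the residue numbering convention of
#' structure papers.
#'
#' @param sequence A single protein sequence string.
#' @param pattern Motif over one-letter codes plus wildcard `X`, e.g.
#'   `"NLTXXH"` or `"YERG"`.
#' @return A tibble `start`, `matched`.
#' @examples
#' scan_motif("GNLTDHHR", "NLTXXH")  # hit at 2
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  pattern <- validate_motif(pattern)
  seq_up <- toupper(gsub("[[:space:]]", "", sequence))
  L <- nchar(pattern)
  if (L == 0 || nchar(seq_up) < L) {
    return(tibble(start = integer(), matched = character()))
  }
  rx <- sprintf("(?=%s)", gsub("X", ".", pattern, fixed = TRUE))
  m <- gregexpr(rx, seq_up, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(start = integer(), matched = character()))
  }
  starts <- as.integer(m)
  tibble(start = starts,
         matched = substring(seq_up, starts, starts + L - 1))
}

#' Scan every sequence of a FASTA table for a motif
#'
#' @param fasta Tibble from [read_fasta()] (columns `id`, `sequence`).
#' @param pattern Motif pattern as in [scan_motif()].
#' @return A tibble `seq_id`, `start`, `matched`, `pattern`.
#' @export
scan_motifs <- function(fasta, pattern) {
  check_columns(fasta, c("id", "sequence"), "fasta")
  purrr::map_dfr(seq_len(nrow(fasta)), function(i) {
    hits <- scan_motif(fasta$sequence[i], pattern)
    if (nrow(hits) == 0) return(NULL)
    dplyr::mutate(hits, seq_id = fasta$id[i],
                  pattern = toupper(pattern)) |>
      dplyr::select("seq_id", "start", "matched", "pattern")
  })
}

#' Write motif hits as TSV
#'
#' Columns `seq_id,start,matched,pattern`.
#'
#' @param hits Tibble from [scan_motifs()].
#' @param path Output file.
#' @return `hits`, invisibly.
#' @export
write_motif_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(hits)
}
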