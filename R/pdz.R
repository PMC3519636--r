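#' Scan protein C-termini for Class I PDZ-binding motifs
#'
#' Class I PDZ-binding motifs are C-terminal 4-mers (positions -3..0)
#' matching S/T at -2 and a hydrophobic residue at 0; the archetypal
#' consensus scanned here is `-3 in {E, D}, -2 in {S, T}, -1 any,
#' 0 in {V, L, I}`. A sequence whose terminal 4-mer deviates from the
#' consensus at exactly one constrained position, by a substitution in the
#' allowed table, is called `near_consensus`; otherwise `none`.
#'
#' The default allowed-substitution table (-3: H, Q; -2: F, G; 0: F) is
#' reverse-engineered from observed near-consensus Shaker C-termini rather
#' than from a general conservation rule, and — like the consensus itself —
#' is fully overridable. Note the acidic tolerance at -3 (D accepted as
#' consensus) is the default's reading of the ambiguous -DGFV case.
#'
#' @param x Protein sequences: a named character vector, a
#'   `Biostrings::AAStringSet`, or the path to a FASTA file (read with
#'   Biostrings when available).
#' @param consensus Named list of allowed residues per position `"-3"`,
#'   `"-2"`, `"-1"` (NULL = any), `"0"`.
#' @param allowed Named list of allowed single substitutions per constrained
#'   position.
#' @return A tibble: `sequence_id`, `c_terminal_4mer`, `call` (factor:
#'   consensus / near_consensus / none), `substitution_position` (-3..0
#'   integer, NA unless near_consensus).
#' @examples
#' pdz_scan(c(NvShak2 = "MAKETLL", NvShak1 = "MAKHTTV", ctrl = "MAKAAAA"))
#' @export
pdz_scan <- function(x,
                     consensus = list(`-3` = c("E", "D"), `-2` = c("S", "T"),
                                      `-1` = NULL, `0` = c("V", "L", "I")),
                     allowed = list(`-3` = c("H", "Q"), `-2` = c("F", "G"),
                                    `0` = c("F"))) {
  seqs <- .as_protein_strings(x)
  if (any(nchar(seqs) < 4)) abort("All sequences must be at least 4 residues long.")
  aa_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (!all(aa_ok)) {
    abort(sprintf("Non-standard amino-acid residues in sequence(s): %s",
                  paste(names(seqs)[!aa_ok], collapse = ", ")))
  }
  positions <- c("-3", "-2", "-1", "0")
  purrr::map_dfr(seq_along(seqs), function(k) {
    fourmer <- substr(seqs[[k]], nchar(seqs[[k]]) - 3L, nchar(seqs[[k]]))
    res <- strsplit(fourmer, "")[[1]]
    deviates <- vapply(seq_along(positions), function(p) {
      allowed_res <- consensus[[positions[[p]]]]
      !is.null(allowed_res) && !(res[[p]] %in% allowed_res)
    }, logical(1))
    call <- "none"
    sub_pos <- NA_integer_
    if (!any(deviates)) {
      call <- "consensus"
    } else if (sum(deviates) == 1L) {
      p <- which(deviates)
      tbl <- allowed[[positions[[p]]]]
      if (!is.null(tbl) && res[[p]] %in% tbl) {
        call <- "near_consensus"
        sub_pos <- p - 4L  # positions -3..0
      }
    }
    tibble::tibble(
      sequence_id = names(seqs)[[k]],
      c_terminal_4mer = fourmer,
      call = factor(call, levels = c("consensus", "near_consensus", "none")),
      substitution_position = sub_pos
    )
  })
}

# Coerce sequences to a named character vector of uppercase residues.
.as_protein_strings <- function(x) {
  if (is.character(x) && length(x) == 1L && !is.null(x) && file.exists(x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading FASTA files requires the Biostrings package.")
    }
    aa <- Biostrings::readAAStringSet(x)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
  } else if (inherits(x, "AAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    abort("`x` must be sequences (named character / AAStringSet) or a FASTA path.")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  toupper(seqs)
}
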