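# Internal genetic-code helpers. Codons are handled internally in the RNA
# alphabet (ACGU, uppercase); DNA input is accepted and normalized.

rna_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  code <- as.character(gc)
  names(code) <- chartr("T", "U", names(gc))
  code
}

all_codons <- function() names(rna_genetic_code())

stop_codons <- function() {
  code <- rna_genetic_code()
  names(code)[code == "*"]
}

sense_codons <- function() setdiff(all_codons(), stop_codons())

# codon -> sorted character vector of its synonymous sense codons
synonym_sets <- function() {
  code <- rna_genetic_code()
  sense <- code[code != "*"]
  lapply(split(names(sense), sense), sort)
}

normalize_codon <- function(x) chartr("T", "U", toupper(x))

# Validate and normalize a CDS string; returns the vector of RNA codons.
# `what` names the argument in error messages.
cds_codons <- function(cds, what = "cds") {
  if (length(cds) != 1L || !is.character(cds)) {
    stop(sprintf("`%s` must be a single character string", what), call. = FALSE)
  }
  seq <- gsub("[[:space:]]", "", cds)
  seq <- normalize_codon(seq)
  n <- nchar(seq)
  if (n == 0L) stop(sprintf("`%s` is empty", what), call. = FALSE)
  if (n %% 3L != 0L) {
    stop(sprintf("coding-frame error: `%s` has %d nucleotides, not a multiple of 3",
                 what, n), call. = FALSE)
  }
  bad <- gsub("[ACGU]", "", seq)
  if (nchar(bad) > 0L) {
    stop(sprintf("alphabet error: `%s` contains characters outside ACGT/ACGU: %s",
                 what, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# TRUE when the original sequence used the DNA alphabet (contains T, no U)
is_dna_alphabet <- function(cds) {
  s <- toupper(cds)
  grepl("T", s, fixed = TRUE) && !grepl("U", s, fixed = TRUE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Utility used by the recoding routines and their tests. Stop codons
#' translate to `*`.
#'
#' @param cds A coding sequence (DNA or RNA alphabet); length must be a
#'   multiple of 3.
#' @return A single amino-acid string.
#' @export
translate_cds <- function(cds) {
  paste(rna_genetic_code()[cds_codons(cds)], collapse = "")
}
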