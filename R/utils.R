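# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Classed error so callers can distinguish data problems from usage problems.
mlst_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mlst_error")))
}

mlst_warn <- function(msg, class = "mlst_warning") {
  warning(warningCondition(msg, class = c(class, "mlst_warning")))
}

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

is_acgt <- function(x) {
  grepl("^[ACGT]+$", x)
}

is_iupac <- function(x) {
  grepl(sprintf("^[%s]+$", paste(IUPAC_CODES, collapse = "")), x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length sequences into a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    mlst_stop("sequences are not all the same length (indels are unsupported)",
              "mlst_length_error")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
         nrow = length(seqs), byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
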