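# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulations never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_undefined_ld <- function(msg) {
  stop(structure(
    class = c("ldrefine_undefined_ld", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse-complement a plain character vector of DNA sequences (IUPAC-aware
# via Biostrings; N and lower case preserved up to case normalization).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Canonical unordered label for the junction of two block/scaffold ends.
adjacency_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

terminal_label <- function(scaffold_id, end) paste(scaffold_id, end, sep = ":")

# Ends of an oriented component: the end that trails when read left to right,
# and the end that leads.
trailing_end <- function(strand) ifelse(strand == "+", "tail", "head")
leading_end <- function(strand) ifelse(strand == "+", "head", "tail")
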