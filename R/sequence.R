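# Protein sequences, variants and region bookkeeping.
#
# Positions are 1-based throughout, matching the residue numbering used in
# NMR and structural work on alpha-synuclein.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 140-residue human alpha-synuclein, Met1 start, no N-acetylation.
ASYN_WT <- paste0(
  "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVH",
  "GVATVAEKTKEQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQL",
  "GKNEEGAPQEGILEDMPVDPDNEAYEMPSEEGYQDYEPEA")

#' Wild-type alpha-synuclein sequence
#'
#' Returns the 140-residue human alpha-synuclein sequence (Met1 start form,
#' no N-terminal acetylation). The same sequence ships as a FASTA file under
#' `inst/extdata/asyn_wt.fasta`.
#'
#' @return A single character string of length-140 one-letter codes.
#' @export
asyn_sequence <- function() ASYN_WT

#' Parse a plus-separated variant specification
#'
#' Variant strings follow the usual point-substitution notation, e.g.
#' `"E114Q+E123Q+E126Q+E137Q+E139Q"` for the 5Q mutant in which five
#' glutamates of the acidic C-terminal tail are replaced by glutamine.
#'
#' @param text Variant string; tokens `<wt><position><new>` joined by `+`.
#'   An empty string (or `NULL`) yields an empty substitution table.
#' @return A data.frame with columns `wt`, `position`, `new`, ordered by
#'   position.
#' @examples
#' parse_variant_spec("E114Q+E123Q")
#' @export
parse_variant_spec <- function(text) {
  empty <- data.frame(wt = character(), position = integer(),
                      new = character(), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(trimws(text))) return(empty)
  tokens <- strsplit(trimws(text), "+", fixed = TRUE)[[1]]
  parsed <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok))[[1]]
    if (length(m) != 4L)
      stop("malformed variant token: '", tok, "'", call. = FALSE)
    wt <- toupper(m[2]); new <- toupper(m[4])
    if (!wt %in% AA_LETTERS || !new %in% AA_LETTERS)
      stop("variant token '", tok, "' uses a non-standard residue letter",
           call. = FALSE)
    data.frame(wt = wt, position = as.integer(m[3]), new = new,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parsed)
  out <- out[order(out$position), , drop = FALSE]
  if (anyDuplicated(out$position))
    stop("duplicate substitution position in variant spec", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply substitutions to a sequence
#'
#' @param sequence One-letter amino-acid string.
#' @param substitutions Data.frame as returned by [parse_variant_spec()].
#' @return The mutated sequence; length is unchanged and only the listed
#'   positions differ.
#' @export
apply_variant <- function(sequence, substitutions) {
  chars <- strsplit(sequence, "")[[1]]
  if (nrow(substitutions) == 0L) return(sequence)
  for (i in seq_len(nrow(substitutions))) {
    pos <- substitutions$position[i]
    if (pos < 1L || pos > length(chars))
      stop("substitution position ", pos, " outside sequence of length ",
           length(chars), call. = FALSE)
    if (chars[pos] != substitutions$wt[i])
      stop("wild-type mismatch at position ", pos, ": sequence has '",
           chars[pos], "', variant expects '", substitutions$wt[i], "'",
           call. = FALSE)
    chars[pos] <- substitutions$new[i]
  }
  paste(chars, collapse = "")
}

default_region_bounds <- function(length) {
  if (length < 101L)
    stop("default region bounds require a sequence of at least 101 residues; ",
         "supply region_bounds explicitly", call. = FALSE)
  data.frame(region = c("nterm", "core", "ctail"),
             start = c(1L, 29L, 101L),
             end = c(28L, 100L, length),
             stringsAsFactors = FALSE)
}

#' Construct a protein specification
#'
#' Bundles a sequence, an optional variant, and the three-region partition
#' used for alpha-synuclein: the N-terminal amphipathic region (1-28), the
#' fibril core (29-100) and the acidic C-terminal tail (101-140).
#'
#' @param name Label (e.g. `"wt"`, `"5Q"`).
#' @param sequence One-letter string; defaults to wild-type alpha-synuclein.
#' @param variant Variant string (see [parse_variant_spec()]), a
#'   substitutions data.frame, or `NULL`. The shorthand `"5Q"` expands to
#'   `"E114Q+E123Q+E126Q+E137Q+E139Q"`.
#' @param region_bounds Data.frame with columns `region`, `start`, `end`
#'   partitioning `1..nchar(sequence)`; defaults to the alpha-synuclein
#'   regions above.
#' @return An object of class `protein_spec`.
#' @examples
#' wt <- protein_spec("wt")
#' q5 <- protein_spec("5Q", variant = "5Q")
#' @export
protein_spec <- function(name = "wt", sequence = asyn_sequence(),
                         variant = NULL, region_bounds = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% AA_LETTERS))
    stop("sequence contains non-standard letters: ",
         paste(unique(chars[!chars %in% AA_LETTERS]), collapse = ","),
         call. = FALSE)
  if (is.character(variant) && length(variant) == 1L &&
      toupper(variant) == "5Q")
    variant <- "E114Q+E123Q+E126Q+E137Q+E139Q"
  subs <- if (is.data.frame(variant)) variant else parse_variant_spec(variant)
  mutated <- apply_variant(sequence, subs)
  if (is.null(region_bounds))
    region_bounds <- default_region_bounds(nchar(sequence))
  stopifnot(all(c("region", "start", "end") %in% names(region_bounds)))
  covered <- unlist(Map(seq.int, region_bounds$start, region_bounds$end))
  if (!identical(sort(covered), seq_len(nchar(sequence))))
    stop("region bounds must partition 1..", nchar(sequence), call. = FALSE)
  structure(list(name = name, sequence = mutated, wt_sequence = sequence,
                 substitutions = subs, region_bounds = region_bounds),
            class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat("protein_spec '", x$name, "': ", nchar(x$sequence), " residues, ",
      nrow(x$substitutions), " substitution(s)\n", sep = "")
  invisible(x)
}

region_of <- function(positions, region_bounds) {
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(region_bounds))) {
    hit <- positions >= region_bounds$start[i] & positions <= region_bounds$end[i]
    out[hit] <- region_bounds$region[i]
  }
  out
}

#' Read / write protein sequences as FASTA
#'
#' Thin wrappers around Biostrings for single-record protein FASTA files.
#'
#' @param path File path.
#' @return `read_fasta` returns a named character vector of sequences;
#'   `write_fasta` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' @param sequences Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
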