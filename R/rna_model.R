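# ---- RNA sequence / secondary-structure model -------------------------------
#
# Internal coordinates are 0-based half-open; every user-facing report uses
# 1-based inclusive coordinates (motif labels like GGA_39-41).

#' Build a pair table from a dot-bracket string
#'
#' Matches nested `()` pairs of a pseudoknot-free secondary structure.
#'
#' @param structure Dot-bracket string using only `.`, `(` and `)`.
#' @return Integer vector of length `nchar(structure)`; element `i` holds the
#'   0-based index of the partner of position `i - 1`, or `NA` if unpaired.
#' @examples
#' build_pair_table("((...))")
#' @export
build_pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad) > 0) {
    stop("illegal structure character(s): ", paste(sQuote(bad), collapse = ", "),
         " (only pseudoknot-free '.', '(', ')' are supported)", call. = FALSE)
  }
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced structure: unmatched ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced structure: unmatched '(' at position ", stack[1], call. = FALSE)
  }
  partner
}

normalize_rna_sequence <- function(sequence, what = "sequence") {
  seq_up <- toupper(sequence)
  seq_up <- gsub("T", "U", seq_up, fixed = TRUE)
  bad <- setdiff(unique(strsplit(seq_up, "", fixed = TRUE)[[1]]), c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    stop("illegal ", what, " character(s): ", paste(sQuote(bad), collapse = ", "),
         " (alphabet is A, C, G, U; T is accepted and read as U)", call. = FALSE)
  }
  seq_up
}

#' Construct an RNA molecule with sequence and secondary structure
#'
#' @param name Identifier.
#' @param sequence RNA sequence (case-insensitive; `T` is normalized to `U`;
#'   IUPAC ambiguity codes are rejected).
#' @param structure Dot-bracket string of the same length, pseudoknot-free.
#' @return An object of class `rna_molecule` with elements `name`, `sequence`,
#'   `structure`, `pairs` (0-based pair table, `NA` = unpaired) and `length`.
#' @examples
#' rna_molecule("hairpin", "GGAAACC", "((...))")
#' @export
rna_molecule <- function(name, sequence, structure) {
  sequence <- normalize_rna_sequence(sequence)
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence (", nchar(sequence), " nt) and structure (", nchar(structure),
         " characters) differ in length for record ", sQuote(name), call. = FALSE)
  }
  pairs <- build_pair_table(structure)
  structure(
    list(name = as.character(name), sequence = sequence, structure = structure,
         pairs = pairs, length = nchar(sequence)),
    class = "rna_molecule"
  )
}

#' @export
print.rna_molecule <- function(x, ...) {
  cat("<rna_molecule> ", x$name, " (", x$length, " nt, ",
      sum(!is.na(x$pairs)) / 2, " base pairs)\n", sep = "")
  cat(" ", x$sequence, "\n ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Parse multi-record Vienna dot-bracket text
#'
#' Each record is a header line (`>name`), a sequence line and a structure
#' line. Plain FASTA (no structure lines) is rejected with a pointer to
#' supplying structures.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return List of [rna_molecule()] objects, in input order.
#' @examples
#' parse_vienna(">x\nGGAAACC\n((...))")
#' @export
parse_vienna <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no records in input", call. = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    stop("parse error at line 1: expected a '>' header line", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[k]])
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 2L) {
      stop("parse error in record ", sQuote(name), " (line ", starts[k],
           "): expected exactly one sequence line and one structure line, got ",
           length(body), " line(s)", call. = FALSE)
    }
    if (!grepl("[.()]", body[2])) {
      stop("record ", sQuote(name), " has no structure line; ",
           "FASTA-only input requires a separately supplied structure", call. = FALSE)
    }
    mol <- tryCatch(
      rna_molecule(name, gsub("\\s", "", body[1]), gsub("\\s", "", body[2])),
      error = function(e) {
        stop("parse error in record ", sQuote(name), " (line ", starts[k], "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    out[[k]] <- mol
  }
  out
}

#' Read a Vienna dot-bracket file
#' @param path File path.
#' @return List of [rna_molecule()] objects.
#' @export
read_vienna <- function(path) parse_vienna(readLines(path, warn = FALSE))

#' Serialize molecules back to Vienna text
#' @param molecules A single [rna_molecule()] or a list of them.
#' @return Character scalar of multi-record Vienna text.
#' @export
format_vienna <- function(molecules) {
  if (inherits(molecules, "rna_molecule")) molecules <- list(molecules)
  paste(vapply(molecules, function(m) {
    paste0(">", m$name, "\n", m$sequence, "\n", m$structure)
  }, character(1)), collapse = "\n")
}

#' Write molecules to a Vienna dot-bracket file
#' @inheritParams format_vienna
#' @param path Output path.
#' @export
write_vienna <- function(molecules, path) {
  writeLines(format_vienna(molecules), path)
  invisible(path)
}

# stem length: contiguous stacked pairs below (and including) the closing
# pair; a bulge on either strand ends the count
stem_length_below <- function(pairs, i, j) {
  n <- 0L
  while (i >= 0L && j < length(pairs) &&
         !is.na(pairs[i + 1L]) && pairs[i + 1L] == j) {
    n <- n + 1L
    i <- i - 1L
    j <- j + 1L
  }
  n
}

#' Local structural context of an unpaired position
#'
#' Identifies whether a position lies in a hairpin loop (a maximal unpaired
#' run whose two flanking positions form the closing base pair), in some
#' other unpaired region (exterior, internal loop or bulge — all reported as
#' single-stranded), or inside a helix.
#'
#' @param rna An [rna_molecule()].
#' @param pos 0-based position.
#' @return A list of class `loop_context` with elements `kind` (`"hairpin"`,
#'   `"single_stranded"` or `"paired"`), `loop_start`, `loop_end` (0-based
#'   half-open span of the unpaired run), `closing_pair` (two-character string
#'   such as `"C-G"`, 5' base first, or `NA`), `penultimate_pair` (the next
#'   pair down the stem or `NA`), and `stem_length` (contiguous stacked pairs
#'   supporting the loop, counting the closing pair).
#' @examples
#' m <- rna_molecule("sl", "GGCUACGGAUAGCC", "((((......))))")
#' hairpin_context(m, 6)
#' @export
hairpin_context <- function(rna, pos) {
  stopifnot(inherits(rna, "rna_molecule"))
  if (pos < 0L || pos >= rna$length) {
    stop("position ", pos, " out of range for ", sQuote(rna$name),
         " (length ", rna$length, ")", call. = FALSE)
  }
  pairs <- rna$pairs
  if (!is.na(pairs[pos + 1L])) {
    return(structure(list(kind = "paired", loop_start = NA_integer_,
                          loop_end = NA_integer_, closing_pair = NA_character_,
                          penultimate_pair = NA_character_, stem_length = 0L),
                     class = "loop_context"))
  }
  # maximal unpaired run containing pos
  s <- pos
  while (s > 0L && is.na(pairs[s])) s <- s - 1L            # pairs[s] is (s-1) 0-based
  e <- pos
  while (e < rna$length - 1L && is.na(pairs[e + 2L])) e <- e + 1L
  loop_start <- if (is.na(pairs[s + 1L])) s else s + 1L    # handle run at 5' end
  loop_end <- e + 1L                                       # half-open
  left <- loop_start - 1L
  right <- loop_end
  is_hairpin <- left >= 0L && right < rna$length &&
    !is.na(pairs[left + 1L]) && pairs[left + 1L] == right &&
    (loop_end - loop_start) >= 3L
  base <- function(i) substr(rna$sequence, i + 1L, i + 1L)
  if (!is_hairpin) {
    return(structure(list(kind = "single_stranded", loop_start = loop_start,
                          loop_end = loop_end, closing_pair = NA_character_,
                          penultimate_pair = NA_character_, stem_length = 0L),
                     class = "loop_context"))
  }
  closing <- paste0(base(left), "-", base(right))
  stem_n <- stem_length_below(pairs, left, right)
  penult <- if (stem_n >= 2L) paste0(base(left - 1L), "-", base(right + 1L)) else NA_character_
  structure(list(kind = "hairpin", loop_start = loop_start, loop_end = loop_end,
                 closing_pair = closing, penultimate_pair = penult,
                 stem_length = stem_n),
            class = "loop_context")
}

#' Count base-paired positions in a span
#'
#' @param rna An [rna_molecule()].
#' @param start,end 0-based half-open span.
#' @return Named integer vector `c(n_paired, n_total)`.
#' @export
pairing_status <- function(rna, start, end) {
  stopifnot(inherits(rna, "rna_molecule"))
  if (end <= start) stop("empty span [", start, ", ", end, ")", call. = FALSE)
  if (start < 0L || end > rna$length) {
    stop("span [", start, ", ", end, ") out of range for ", sQuote(rna$name),
         call. = FALSE)
  }
  idx <- (start + 1L):end
  c(n_paired = sum(!is.na(rna$pairs[idx])), n_total = length(idx))
}
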