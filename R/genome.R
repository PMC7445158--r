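#' Gene kind labels
#'
#' Genomes are integer matrices with one row per gene and columns
#' \code{kind}, \code{a}, \code{b}.  \code{kind} indexes into
#' \code{GENE_KINDS}; the meaning of \code{a} and \code{b} depends on it:
#' an INPUT gene reads puzzle bit \code{a}; an OUTPUT gene writes register
#' \code{a} from the value stored at genome position \code{b}; a NAND gene
#' combines the values stored at positions \code{a} and \code{b}; a
#' CELLULARITY gene has no fields and passes through the preceding value.
#' Pointer-valued fields are absolute 0-based genome positions, strictly
#' smaller than the gene's own position; \code{NA} means unset and reads as
#' the value 0 during execution.
#' @export
GENE_KINDS <- c("INPUT", "OUTPUT", "NAND", "CELLULARITY")

#' Construct a genome from gene fields
#'
#' @param kind integer vector of gene kind codes (1 = INPUT, 2 = OUTPUT,
#'   3 = NAND, 4 = CELLULARITY), or a character vector of kind names.
#' @param a,b integer vectors of per-gene fields (see [GENE_KINDS]);
#'   \code{NA} = unset.
#' @return A \code{cm_genome} object.
#' @examples
#' g <- new_genome(c("INPUT", "OUTPUT"), a = c(0L, 0L), b = c(NA, 0L))
#' genome_length(g)
#' @export
new_genome <- function(kind, a = NA_integer_, b = NA_integer_) {
  if (is.character(kind)) kind <- match(kind, GENE_KINDS)
  n <- length(kind)
  m <- cbind(kind = as.integer(kind), a = rep_len(as.integer(a), n),
             b = rep_len(as.integer(b), n))
  as_genome(m)
}

as_genome <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  storage.mode(m) <- "integer"
  colnames(m) <- c("kind", "a", "b")
  class(m) <- c("cm_genome", "matrix", "array")
  m
}

#' Genome accessors
#'
#' @param genome a \code{cm_genome}.
#' @return \code{genome_length()}: the number of genes L;
#'   \code{n_cellularity_genes()}: the number of CELLULARITY genes;
#'   \code{gene_kinds()}: a character vector of kind names.
#' @export
genome_length <- function(genome) nrow(genome)

#' @rdname genome_length
#' @export
n_cellularity_genes <- function(genome) sum(genome[, 1L] == 4L)

#' @rdname genome_length
#' @export
gene_kinds <- function(genome) GENE_KINDS[genome[, 1L]]

#' Construct a founder genome
#'
#' The founder genome is a hybrid designed/random network: 8 INPUT genes
#' reading puzzle bits 0..7 (one each), 16 NAND genes whose operand pointers
#' are drawn uniformly from the preceding positions (the randomized Boolean
#' circuit), 8 OUTPUT genes writing registers 0..7 (one each) with source
#' pointers initialized to the immediately preceding position, and
#' \code{n_cellularity} CELLULARITY genes appended at the end.
#'
#' @param n_cellularity number of cellularity genes to append (0 or 3 in the
#'   standard scenarios).
#' @return A \code{cm_genome} of length \code{32 + n_cellularity}.
#' @examples
#' set.seed(1)
#' g <- founder_genome(3)
#' genome_length(g)       # 35
#' n_cellularity_genes(g) # 3
#' @export
founder_genome <- function(n_cellularity = 0) {
  stopifnot(length(n_cellularity) == 1L, n_cellularity >= 0)
  as_genome(cpp_founder_genome(as.integer(n_cellularity)))
}

#' Validate genome invariants
#'
#' Checks that every gene's fields are in range: input/output register
#' indices in 0..7, and every set pointer strictly smaller than the gene's
#' own 0-based position.
#'
#' @param genome a \code{cm_genome}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_genome <- function(genome) {
  kind <- genome[, 1L]; a <- genome[, 2L]; b <- genome[, 3L]
  pos <- seq_len(nrow(genome)) - 1L  # 0-based own position
  if (!all(kind %in% 1:4)) stop("invalid gene kind code")
  ok_idx <- function(v) all(is.na(v) | (v >= 0L & v <= 7L))
  ok_ptr <- function(v) all(is.na(v) | (v >= 0L & v < pos))
  if (!ok_idx(a[kind == 1L])) stop("INPUT index out of range")
  if (!ok_idx(a[kind == 2L])) stop("OUTPUT register index out of range")
  if (any(kind == 2L) && !all(is.na(b[kind == 2L]) |
      (b[kind == 2L] >= 0L & b[kind == 2L] < pos[kind == 2L])))
    stop("OUTPUT source pointer not strictly preceding")
  nan_ok <- kind == 3L
  if (any(nan_ok)) {
    p <- pos[nan_ok]
    for (v in list(a[nan_ok], b[nan_ok]))
      if (!all(is.na(v) | (v >= 0L & v < p)))
        stop("NAND operand pointer not strictly preceding")
  }
  invisible(TRUE)
}

#' Hand-constructed reference genomes
#'
#' \code{not_network_genome()} builds, for each puzzle bit k, an INPUT gene
#' reading bit k, a NAND gene with both operands on that input (computing
#' NOT), and an OUTPUT gene writing register k from the NAND.  It solves
#' every puzzle perfectly (metabolic proficiency 8).
#' \code{copy_through_genome()} wires each OUTPUT directly to its INPUT and
#' so returns the puzzle input itself (proficiency 0, since the solution is
#' the complement).
#'
#' @return A \code{cm_genome}.
#' @examples
#' measure_proficiency(not_network_genome(), 100) # exactly 8
#' @export
not_network_genome <- function() {
  kind <- integer(0); a <- integer(0); b <- integer(0)
  pos <- 0L
  for (k in 0:7) {
    kind <- c(kind, 1L, 3L, 2L)
    a <- c(a, k, pos, k)
    b <- c(b, NA_integer_, pos, pos + 1L)
    pos <- pos + 3L
  }
  new_genome(kind, a, b)
}

#' @rdname not_network_genome
#' @export
copy_through_genome <- function() {
  kind <- integer(0); a <- integer(0); b <- integer(0)
  pos <- 0L
  for (k in 0:7) {
    kind <- c(kind, 1L, 2L)
    a <- c(a, k, k)
    b <- c(b, NA_integer_, pos)
    pos <- pos + 2L
  }
  new_genome(kind, a, b)
}

format_gene_tokens <- function(genome) {
  kind <- genome[, 1L]; a <- genome[, 2L]; b <- genome[, 3L]
  dash <- function(v) ifelse(is.na(v), "-", as.character(v))
  tok <- character(nrow(genome))
  tok[kind == 1L] <- paste0("I", a[kind == 1L])
  tok[kind == 2L] <- paste0("O", dash(b[kind == 2L]), ">", a[kind == 2L])
  tok[kind == 3L] <- paste0("N", dash(a[kind == 3L]), ",", dash(b[kind == 3L]))
  tok[kind == 4L] <- "C"
  tok
}

#' @export
print.cm_genome <- function(x, ...) {
  cat(sprintf("<genome: %d genes, %d cellularity>\n", nrow(x),
              n_cellularity_genes(x)))
  cat(paste(format_gene_tokens(x), collapse = " "), "\n")
  invisible(x)
}

#' Read and write genomes as plain text
#'
#' One genome per line, whitespace-separated gene tokens; lines starting with
#' \code{#} are comments.  Tokens: \code{I<k>} (INPUT reading puzzle bit k),
#' \code{N<a>,<b>} (NAND with absolute 0-based operand positions, \code{-}
#' for unset), \code{O<s>><k>} (OUTPUT sourcing position s into register k;
#' \code{O->k} when the source is unset), \code{C} (CELLULARITY).
#'
#' @param genomes a list of \code{cm_genome} objects (or a single genome).
#' @param path file path.
#' @return \code{read_genomes()}: a list of \code{cm_genome}s.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "cm_genome")) genomes <- list(genomes)
  lines <- vapply(genomes, function(g) paste(format_gene_tokens(g),
                                             collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lapply(which(keep), function(i) parse_genome_line(lines[i], i))
}

parse_genome_line <- function(line, lineno = NA) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  int_or_na <- function(s) if (s == "-") NA_integer_ else as.integer(s)
  kind <- integer(length(toks)); a <- integer(length(toks))
  b <- integer(length(toks))
  for (j in seq_along(toks)) {
    t <- toks[j]
    if (grepl("^I[0-7]$", t)) {
      kind[j] <- 1L; a[j] <- as.integer(sub("^I", "", t)); b[j] <- NA_integer_
    } else if (grepl("^O([0-9]+|-)>[0-7]$", t)) {
      kind[j] <- 2L
      parts <- strsplit(sub("^O", "", t), ">", fixed = TRUE)[[1]]
      a[j] <- as.integer(parts[2]); b[j] <- int_or_na(parts[1])
    } else if (grepl("^N([0-9]+|-),([0-9]+|-)$", t)) {
      kind[j] <- 3L
      parts <- strsplit(sub("^N", "", t), ",", fixed = TRUE)[[1]]
      a[j] <- int_or_na(parts[1]); b[j] <- int_or_na(parts[2])
    } else if (t == "C") {
      kind[j] <- 4L; a[j] <- NA_integer_; b[j] <- NA_integer_
    } else {
      stop(sprintf("malformed gene token '%s' (line %s, token %d)",
                   t, lineno, j))
    }
  }
  g <- new_genome(kind, a, b)
  validate_genome(g)
  g
}
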