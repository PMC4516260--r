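#' The 21-symbol alignment alphabet
#'
#' Twenty standard amino acids plus the gap character \code{"-"}.  The gap is
#' a first-class symbol: frequency estimation, mutual information and the
#' direct-coupling analysis all sum over 21 states.
#'
#' @return Character vector of length 21.
#' @export
coev_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

N_SYMBOLS <- 21L

#' Construct a validated multiple sequence alignment
#'
#' An alignment is stored as a character matrix with one row per species and
#' one column per alignment position.  All rows must have equal length, all
#' symbols must belong to the 21-letter alphabet (ambiguity codes such as
#' B, J, O, U, X, Z are rejected rather than coerced), and species
#' identifiers must be unique.  Lower-case input is upper-cased and the
#' alternative gap character \code{"."} is normalized to \code{"-"}.
#'
#' @param seqs Character vector of aligned sequences (one string per
#'   species), or a character matrix of single symbols.
#' @param species Character vector of unique species identifiers, one per
#'   sequence.  Ignored when \code{seqs} is a matrix with row names.
#' @return An object of class \code{coev_aln}: a character matrix with
#'   species as row names.
#' @export
alignment <- function(seqs, species = names(seqs)) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (!is.null(rownames(m))) species <- rownames(m)
  } else {
    if (is.null(species)) stop("species identifiers are required")
    if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) {
      stop("aligned sequences differ in length (", paste(unique(n), collapse = ", "),
           "); rows of an alignment must be equal-length")
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (anyDuplicated(species)) {
    stop("duplicate species identifiers: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  m[] <- toupper(m)
  m[m == "."] <- "-"
  bad <- !(m %in% coev_alphabet())
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m), ncol(m)), arr.ind = TRUE)[1L, ]
    stop("symbol '", m[idx[1L], idx[2L]], "' outside the 21-letter alphabet ",
         "(species '", species[idx[1L]], "', column ", idx[2L], ")")
  }
  rownames(m) <- species
  colnames(m) <- NULL
  structure(m, class = c("coev_aln", "matrix", "array"))
}

#' @export
print.coev_aln <- function(x, ...) {
  cat("<coev_aln> ", nrow(x), " species x ", ncol(x), " columns\n", sep = "")
  show <- utils::head(rownames(x), 6L)
  for (sp in show) {
    s <- paste(x[sp, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(format(sp, width = 24L), s, if (ncol(x) > 50L) "..." else "", "\n")
  }
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more species\n", sep = "")
  invisible(x)
}

#' Number of species and columns of an alignment
#'
#' @param a A \code{coev_aln}.
#' @return Integer count.
#' @export
n_species <- function(a) {
  UseMethod("n_species")
}

#' @export
n_species.coev_aln <- function(a) nrow(a)

#' @export
n_species.coev_paired <- function(a) length(a$species)

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file and returns a validated
#' \code{coev_aln}.  Symbols are upper-cased, \code{"."} gaps are normalized
#' to \code{"-"}, and any sequence containing a symbol outside the 21-letter
#' alphabet (e.g. the ambiguity codes B, J, O, U, X, Z) is rejected with an
#' error naming the offending species and column.
#'
#' @param path Path to the alignment file.
#' @param format Either \code{"fasta"} or \code{"clustal"}.
#' @return A \code{coev_aln}.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    aln <- seqinr::read.alignment(path, format = "fasta")
    if (aln$nb < 1L) stop("no sequences found in ", path)
    seqs <- unlist(aln$seq, use.names = FALSE)
    species <- aln$nam
  } else {
    ms <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(ms))
    species <- names(seqs)
  }
  nch <- nchar(seqs)
  if (length(unique(nch)) != 1L) {
    stop("rows of '", path, "' differ in length; not a valid alignment")
  }
  alignment(unname(seqs), species = species)
}

#' Write an alignment as aligned FASTA
#'
#' @param a A \code{coev_aln}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "coev_aln"))
  seqs <- apply(unclass(a), 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(a), file.out = path,
                      nbchar = 60L)
  invisible(path)
}

#' Encode an alignment as integer states
#'
#' Maps each symbol to its index in \code{coev_alphabet()} (gap = 21).
#'
#' @param a A \code{coev_aln}.
#' @return Integer matrix of the same shape.
#' @export
encode_alignment <- function(a) {
  m <- match(unclass(a), coev_alphabet())
  dim(m) <- dim(a)
  rownames(m) <- rownames(a)
  m
}

#' Pair two alignments on their shared species
#'
#' Restricts two alignments to the species present in both (exact identifier
#' match, order taken from the first alignment) and records the column
#' boundary between the two protein blocks.  This is the concatenated-
#' alignment representation used for inter-protein analyses.
#'
#' @param a,b \code{coev_aln} objects.
#' @return A \code{coev_paired}: list with elements \code{a}, \code{b}
#'   (species-matched \code{coev_aln} blocks), \code{species} and
#'   \code{boundary} (the number of columns in block \code{a}).
#' @export
pair_by_species <- function(a, b) {
  stopifnot(inherits(a, "coev_aln"), inherits(b, "coev_aln"))
  shared <- rownames(a)[rownames(a) %in% rownames(b)]
  if (length(shared) == 0L) stop("no species shared between the two alignments")
  pa <- alignment(unclass(a)[shared, , drop = FALSE])
  pb <- alignment(unclass(b)[shared, , drop = FALSE])
  structure(list(a = pa, b = pb, species = shared, boundary = ncol(pa)),
            class = "coev_paired")
}

#' @export
print.coev_paired <- function(x, ...) {
  cat("<coev_paired> ", length(x$species), " shared species; block A ",
      ncol(x$a), " cols, block B ", ncol(x$b), " cols\n", sep = "")
  invisible(x)
}

#' Concatenate the two blocks of a paired alignment
#'
#' @param p A \code{coev_paired}.
#' @return A \code{coev_aln} with \code{boundary} columns of protein A
#'   followed by the columns of protein B.
#' @export
concat_paired <- function(p) {
  stopifnot(inherits(p, "coev_paired"))
  alignment(cbind(unclass(p$a), unclass(p$b)))
}

#' Identify invariant alignment columns
#'
#' A column is invariant when every species holds the same symbol; the gap
#' counts as a symbol, so a column that is gap in every species is invariant.
#' Invariant columns carry no covariation signal and are excluded from all
#' score matrices.
#'
#' @param a A \code{coev_aln}.
#' @return Logical vector, \code{TRUE} for invariant columns.
#' @export
invariant_columns <- function(a) {
  stopifnot(inherits(a, "coev_aln"), nrow(a) >= 1L)
  apply(unclass(a), 2L, function(col) all(col == col[1L]))
}

#' Percent identity between two aligned rows
#'
#' Identity is counted over mutually non-gap columns: 100 times the number
#' of columns where both rows hold the same (non-gap) symbol, divided by the
#' number of columns where neither row is gapped.  Reports conventionally
#' round this to the nearest integer.
#'
#' @param a,b Character vectors of aligned symbols (rows of a common
#'   alignment), or single aligned strings.
#' @return Percentage in \code{[0, 100]} (full precision).
#' @export
percent_identity <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  a <- toupper(a); b <- toupper(b)
  a[a == "."] <- "-"; b[b == "."] <- "-"
  if (length(a) != length(b)) stop("rows differ in length; not from a common alignment")
  co <- a != "-" & b != "-"
  if (!any(co)) stop("no mutually non-gap columns; identity undefined")
  100 * sum(a[co] == b[co]) / sum(co)
}

#' Pairwise identity table for an alignment
#'
#' @param a A \code{coev_aln}.
#' @param digits Rounding for the reported percentage (default integer).
#' @return Data frame with columns \code{species_a}, \code{species_b},
#'   \code{pct_identity}.
#' @export
identity_table <- function(a, digits = 0) {
  stopifnot(inherits(a, "coev_aln"))
  sp <- rownames(a)
  idx <- utils::combn(length(sp), 2L)
  data.frame(
    species_a = sp[idx[1L, ]],
    species_b = sp[idx[2L, ]],
    pct_identity = round(apply(idx, 2L, function(ij)
      percent_identity(unclass(a)[ij[1L], ], unclass(a)[ij[2L], ])), digits),
    stringsAsFactors = FALSE
  )
}

#' Map alignment columns to reference-sequence residue numbers
#'
#' Builds the mapping from alignment columns (1-based) to residue numbers
#' (1-based) along the ungapped row of a chosen reference species.  Columns
#' where the reference row is gapped are unmapped.
#'
#' @param a A \code{coev_aln}.
#' @param reference_species Species identifier present in \code{a}.
#' @return A \code{coev_refmap}: list with \code{reference_species} and
#'   \code{column_to_residue}, an integer vector named by alignment column.
#' @export
column_to_reference <- function(a, reference_species) {
  stopifnot(inherits(a, "coev_aln"))
  if (!reference_species %in% rownames(a)) {
    stop("reference species '", reference_species, "' not in alignment")
  }
  row <- unclass(a)[reference_species, ]
  cols <- which(row != "-")
  map <- seq_along(cols)
  names(map) <- cols
  structure(list(reference_species = reference_species,
                 column_to_residue = map),
            class = "coev_refmap")
}

#' Translate alignment columns to reference residue numbers
#'
#' @param refmap A \code{coev_refmap}.
#' @param columns Integer alignment columns (1-based).
#' @return Integer residue numbers; \code{NA} for columns gapped in the
#'   reference row.
#' @export
map_columns <- function(refmap, columns) {
  stopifnot(inherits(refmap, "coev_refmap"))
  unname(refmap$column_to_residue[as.character(columns)])
}

#' Subset an alignment or paired alignment by species
#'
#' Keeps or drops the named species, preserving the original order.
#' Invariant-column masks must be recomputed downstream: removing species
#' can only turn variable columns invariant.
#'
#' @param x A \code{coev_aln} or \code{coev_paired}.
#' @param species Character vector of species identifiers; all must exist.
#' @param mode \code{"keep"} or \code{"drop"}.
#' @return Object of the same class as \code{x}.
#' @export
subset_species <- function(x, species, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  UseMethod("subset_species")
}

#' @export
subset_species.coev_aln <- function(x, species, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  missing <- setdiff(species, rownames(x))
  if (length(missing)) stop("unknown species: ", paste(missing, collapse = ", "))
  keep <- if (mode == "keep") rownames(x) %in% species else !(rownames(x) %in% species)
  if (!any(keep)) stop("subset would leave no species")
  alignment(unclass(x)[keep, , drop = FALSE])
}

#' @export
subset_species.coev_paired <- function(x, species, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  a <- subset_species(x$a, species, mode)
  b <- subset_species(x$b, species, mode)
  pair_by_species(a, b)
}
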