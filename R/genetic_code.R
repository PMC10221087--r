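#' The standard genetic code as an RNA codon table
#'
#' Returns the standard (nuclear) genetic code as a data frame of sense
#' codons, one row per codon, with stop codons removed. Selenocysteine and
#' pyrrolysine are not modelled. The table is derived from
#' \code{Biostrings::GENETIC_CODE} with DNA thymine rewritten as uracil.
#'
#' @return A data frame with columns \code{amino_acid} (1-letter code),
#'   \code{aa3} (3-letter code) and \code{codon} (RNA triplet, 5'->3'),
#'   containing exactly 61 rows.
#' @examples
#' tab <- standard_code_table()
#' nrow(tab)  # 61 sense codons
#' @export
standard_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- chartr("T", "U", names(gc))
  aa <- unname(gc)
  keep <- aa != "*"
  out <- data.frame(amino_acid = aa[keep],
                    aa3 = AA_THREE_LETTER[aa[keep]],
                    codon = codons[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val")

#' Read a genetic-code table from tabular text
#'
#' Reads an alternative code table (e.g. for codon-reassignment
#' experiments) from a whitespace- or tab-delimited file with columns
#' \code{amino_acid} and \code{codon} (RNA, 5'->3'). Stop codons must not
#' be listed.
#'
#' @param path Path to the table file.
#' @return A data frame with the same shape as [standard_code_table()]
#'   (column \code{aa3} is filled where the 1-letter code is standard,
#'   \code{NA} otherwise).
#' @export
read_code_table <- function(path) {
  if (!file.exists(path))
    stop("code table file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "codon") %in% names(tab)))
    stop("code table must have columns `amino_acid` and `codon`",
         call. = FALSE)
  tab$codon <- toupper(chartr("T", "U", tab$codon))
  bad <- tab$codon[!grepl("^[ACGU]{3}$", tab$codon)]
  if (length(bad))
    stop("invalid codon(s) in code table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  data.frame(amino_acid = tab$amino_acid,
             aa3 = unname(AA_THREE_LETTER[tab$amino_acid]),
             codon = tab$codon, stringsAsFactors = FALSE)
}

validate_codon <- function(codon) {
  if (!is.character(codon) || any(is.na(codon)))
    stop("codons must be character strings", call. = FALSE)
  up <- toupper(codon)
  bad <- !grepl("^[ACGU]{3}$", up)
  if (any(bad)) {
    sym <- unique(unlist(strsplit(up[bad], "")))
    sym <- sym[!sym %in% RNA_BASES]
    stop("invalid RNA triplet(s): ", paste(codon[bad], collapse = ", "),
         if (length(sym)) paste0(" (offending symbol(s): ",
                                 paste(sym, collapse = ", "), ")"),
         call. = FALSE)
  }
  up
}

#' Anticodon of an RNA codon
#'
#' Derives the anticodon triplet for one or more codons. Two conventions
#' are supported: \code{"revcomp"} (the default, biological standard)
#' writes the anticodon 5'->3' as the reverse complement of the codon, so
#' anticodon base 1 pairs with codon base 3; \code{"aligned"} writes the
#' position-wise complement, so anticodon base i is the complement of
#' codon base i. Under both conventions the anticodon middle base is the
#' Watson-Crick complement of the codon middle base, and applying the
#' operation twice returns the input.
#'
#' @param codon Character vector of RNA triplets (5'->3').
#' @param convention \code{"revcomp"} or \code{"aligned"}.
#' @return Character vector of anticodon triplets.
#' @examples
#' anticodon_of("UUU")  # "AAA": Phe's anticodon, middle base A
#' anticodon_of("GAC")  # "GUC": Asp, anticodon middle base U
#' @export
anticodon_of <- function(codon, convention = c("revcomp", "aligned")) {
  convention <- match.arg(convention)
  codon <- validate_codon(codon)
  comp <- chartr("ACGU", "UGCA", codon)
  if (convention == "aligned") return(comp)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

codon_base <- function(codon, pos) substr(codon, pos, pos)

# Codon families: distinct first-two-base prefixes per amino acid, with the
# set of third bases seen in each. Hexacodonic amino acids (Arg, Ser, Leu)
# have two families; all others have one.
codon_families <- function(table = standard_code_table()) {
  pre <- substr(table$codon, 1, 2)
  key <- paste(table$amino_acid, pre, sep = ":")
  fam <- lapply(split(seq_len(nrow(table)), key), function(i) {
    list(amino_acid = table$amino_acid[i[1]],
         prefix = substr(table$codon[i[1]], 1, 2),
         third = sort(unique(codon_base(table$codon[i], 3))))
  })
  fam <- fam[order(vapply(fam, function(f)
    paste(f$amino_acid, f$prefix), ""))]
  unname(fam)
}

#' Amino acids encoded by six codons
#'
#' @param table A code table as returned by [standard_code_table()].
#' @return Character vector of 1-letter codes of amino acids spanning more
#'   than one codon family (Arg, Ser, Leu in the standard code).
#' @export
hexacodonic_amino_acids <- function(table = standard_code_table()) {
  fams <- codon_families(table)
  aa <- vapply(fams, `[[`, "", "amino_acid")
  sort(unique(aa[duplicated(aa)]))
}

#' Expand cognate base allocations for a position scheme
#'
#' Builds the allocation list used by the preference statistics: one
#' allocation per amino acid, plus one extra per hexacodonic amino acid
#' (Arg, Ser, Leu), each carrying the set of cognate bases at the chosen
#' codon/anticodon position. The standard table yields 23 allocations.
#'
#' For \code{anticodon1} under the \code{"revcomp"} convention the cognate
#' set is the complement of the codon's (possibly degenerate) third bases
#' and can contain more than one base; every other scheme yields a single
#' base per allocation.
#'
#' @param table A code table.
#' @param position One of \code{"codon1"}, \code{"codon2"},
#'   \code{"anticodon1"}, \code{"anticodon2"}.
#' @param convention Anticodon convention, see [anticodon_of()].
#' @return A data frame with columns \code{amino_acid}, \code{prefix}
#'   (first two codon bases identifying the family), \code{position} and
#'   list-column \code{cognate} (character vector of bases).
#' @examples
#' nrow(expand_assignments(position = "anticodon2"))  # 23
#' @export
expand_assignments <- function(table = standard_code_table(),
                               position = c("anticodon2", "anticodon1",
                                            "codon1", "codon2"),
                               convention = c("revcomp", "aligned")) {
  if (is.character(position) &&
      !all(position %in% c("anticodon2", "anticodon1", "codon1", "codon2")))
    stop("unknown position scheme: ", position[1], call. = FALSE)
  position <- match.arg(position)
  convention <- match.arg(convention)
  fams <- codon_families(table)
  cognate <- lapply(fams, function(f) {
    b1 <- substr(f$prefix, 1, 1)
    b2 <- substr(f$prefix, 2, 2)
    switch(position,
      codon1 = b1,
      codon2 = b2,
      anticodon2 = unname(RNA_COMPLEMENT[b2]),
      anticodon1 = if (convention == "aligned")
        unname(RNA_COMPLEMENT[b1])
      else sort(unique(unname(RNA_COMPLEMENT[f$third]))))
  })
  out <- data.frame(
    amino_acid = vapply(fams, `[[`, "", "amino_acid"),
    prefix = vapply(fams, `[[`, "", "prefix"),
    position = position, stringsAsFactors = FALSE)
  out$cognate <- cognate
  out
}

#' Anticodon middle-base usage across the code
#'
#' Counts, for each base, how many of the amino acids use it as the middle
#' base of their anticodon (equivalently, whose codon middle base is its
#' complement). Amino acids are counted once per distinct middle base, so a
#' hexacodonic amino acid whose two codon families differ at the middle
#' position (Ser) contributes to two bases.
#'
#' @param table A code table.
#' @return Named integer vector over A, C, G, U. In the standard code
#'   U is used by 7 of the 20 amino acids.
#' @export
middle_base_usage <- function(table = standard_code_table()) {
  mids <- split(codon_base(table$codon, 2), table$amino_acid)
  anti_mid <- lapply(mids, function(b) unique(unname(RNA_COMPLEMENT[b])))
  counts <- table(factor(unlist(anti_mid), levels = RNA_BASES))
  out <- as.integer(counts)
  names(out) <- RNA_BASES
  out
}

#' Cognate dinucleotides of an amino acid
#'
#' Distinct base-1 + base-2 pairs across an amino acid's codons
#' (\code{frame = "codonic"}) or anticodons (\code{frame = "anticodonic"}).
#' Under the \code{"aligned"} anticodon convention the anticodonic pairs
#' are third-base independent (the complement of the codonic prefix);
#' under \code{"revcomp"} they reflect the degenerate third base.
#'
#' @param amino_acid 1-letter code.
#' @param frame \code{"codonic"} or \code{"anticodonic"}.
#' @param table A code table.
#' @param convention Anticodon convention, see [anticodon_of()].
#' @return Character vector of 2-base strings, sorted.
#' @examples
#' cognate_dinucleotides("G")  # "GG"
#' cognate_dinucleotides("S")  # "AG" "UC"
#' @export
cognate_dinucleotides <- function(amino_acid,
                                  frame = c("codonic", "anticodonic"),
                                  table = standard_code_table(),
                                  convention = c("revcomp", "aligned")) {
  frame <- match.arg(frame)
  convention <- match.arg(convention)
  codons <- table$codon[table$amino_acid == amino_acid]
  if (!length(codons))
    stop("unknown amino acid: ", amino_acid, call. = FALSE)
  trip <- if (frame == "codonic") codons else
    anticodon_of(codons, convention)
  sort(unique(substr(trip, 1, 2)))
}
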