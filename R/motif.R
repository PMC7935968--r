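## MCR alpha-subunit motif scan. The Tyr444-Gly445-Tyr446 motif of the
## methyl-coenzyme M reductase alpha subunit marks the high-performance
## (Class I) methanogens; Y->F substitutions at 444 or 446 mark Class II
## methanogens and Methanosarcinaceae respectively. Residue numbering
## follows the ungapped coordinates of a designated reference sequence
## (canonically MCR I alpha of Methanothermobacter marburgensis).

.alnMatrix <- function(aln) {
    if (methods::is(aln, "AAMultipleAlignment"))
        aln <- Biostrings::unmasked(aln)
    if (!methods::is(aln, "AAStringSet"))
        aln <- Biostrings::AAStringSet(aln)
    if (length(unique(Biostrings::width(aln))) != 1)
        stop("alignment rows must all have the same (gapped) length")
    aln
}

#' Map reference residue positions to alignment columns
#'
#' The k-th non-gap character of the reference sequence defines residue
#' number k (1-based); this returns, for each requested residue number, the
#' 1-based alignment column it sits in.
#'
#' @param aln a gapped [Biostrings::AAStringSet] (or AAMultipleAlignment).
#' @param referenceId name of the reference sequence in `aln`.
#' @param positions residue numbers to map (default 1..446 minimum
#'   requirement applies to the reference length).
#' @return Integer vector of alignment columns, named by residue number.
#' @export
mapReferencePositions <- function(aln, referenceId, positions = NULL) {
    aln <- .alnMatrix(aln)
    if (!referenceId %in% names(aln))
        stop(sprintf("reference '%s' not found in the alignment", referenceId))
    refChars <- strsplit(as.character(aln[[referenceId]]), "")[[1]]
    nonGap <- which(refChars != "-")
    if (length(nonGap) < 446)
        stop(sprintf(
            "reference has only %d residues; motif numbering needs >= 446",
            length(nonGap)))
    if (is.null(positions)) positions <- seq_along(nonGap)
    if (any(positions < 1 | positions > length(nonGap)))
        stop("requested residue positions fall outside the reference")
    stats::setNames(nonGap[positions], positions)
}

#' Classify the 444-446 motif of every aligned sequence
#'
#' Extracts the residues at the reference-mapped columns 444, 445 and 446
#' for every sequence and assigns a motif class: `YGY` (the
#' high-performance, Class I-associated motif), `FGY` (Y444F, the Class II
#' signature), `YGF` (Y446F, typical of Methanosarcinaceae), `FGF`, or
#' `other/gapped` for anything else including gaps or ambiguous residues.
#' Comparison is case-insensitive; `X` counts as other.
#'
#' @inheritParams mapReferencePositions
#' @param includeReference include the reference row itself (default TRUE).
#' @return A data.frame (the motif report): `id`, `res444`, `res445`,
#'   `res446`, `motif` (3-character string) and `class`.
#' @export
classifyMotifs <- function(aln, referenceId, includeReference = TRUE) {
    aln <- .alnMatrix(aln)
    cols <- mapReferencePositions(aln, referenceId, positions = 444:446)
    ids <- names(aln)
    if (!includeReference) ids <- setdiff(ids, referenceId)
    rows <- lapply(ids, function(id) {
        chars <- strsplit(as.character(aln[[id]]), "")[[1]]
        res <- toupper(chars[cols])
        motif <- paste(res, collapse = "")
        cls <- if (motif %in% c("YGY", "FGY", "YGF", "FGF"))
            motif else "other/gapped"
        data.frame(id = id, res444 = res[1], res445 = res[2],
                   res446 = res[3], motif = motif, class = cls,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Read an aligned FASTA and classify its motifs
#'
#' Thin convenience wrapper: reads a gapped amino-acid FASTA with
#' [Biostrings::readAAStringSet()] and runs [classifyMotifs()].
#'
#' @param path aligned FASTA file.
#' @inheritParams classifyMotifs
#' @return The motif report data.frame.
#' @export
classifyMotifsFasta <- function(path, referenceId, includeReference = TRUE) {
    aln <- Biostrings::readAAStringSet(path)
    classifyMotifs(aln, referenceId, includeReference = includeReference)
}
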