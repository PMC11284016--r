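# Pairwise global alignment wrappers. All sequence comparison in the package
# funnels through these: Needleman-Wunsch with affine gaps (open 10, extend 1)
# and BLOSUM62 scoring; identity is counted on exact residue matches only.

align_global <- function(a, b, gap_open = 10, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(pattern = pat, subject = sub, score = Biostrings::score(aln))
}

# Matches and aligned length between two sequences. Gap columns count toward
# the alignment length (and hence against identity).
alignment_stats <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    return(list(matches = sum(x == y), length = length(x)))
  }
  al <- align_global(a, b)
  keep <- !(al$pattern == "-" & al$subject == "-")
  list(matches = sum(al$pattern[keep] == al$subject[keep] & al$pattern[keep] != "-"),
       length = sum(keep))
}

# Percent identity with a choice of denominator: the full alignment length
# (used for repertoire top-k identity) or the pattern length (used for
# germline-versus-parent framework homology, where the parent FR is the
# pattern).
percent_identity <- function(a, b, denominator = c("alignment", "pattern")) {
  denominator <- match.arg(denominator)
  st <- alignment_stats(a, b)
  denom <- if (denominator == "pattern") nchar(a) else st$length
  100 * st$matches / denom
}

mismatch_count <- function(a, b) {
  st <- alignment_stats(a, b)
  st$length - st$matches
}
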