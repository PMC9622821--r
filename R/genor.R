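# Clustal weak-similarity groups, used for the '.' annotation tier.
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                  "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Build a per-species smORF peptide database
#'
#' In-silico translation of transcript/EST sequences into all AUG->STOP
#' peptides of 10-150 amino acids (6-frame by default, forward 3-frame
#' otherwise), deduplicated by peptide sequence within the species.
#'
#' @param transcripts A [transcript_set()] or named character vector of
#'   nucleotide sequences.
#' @param species Species identifier stored with the database.
#' @param six_frame Scan both strands (default TRUE, EST-style input).
#' @param min_aa,max_aa Peptide length bounds (codon count, stop excluded).
#' @return data.frame (class `smorf_db`) with columns `id`, `peptide`;
#'   attribute `species`.
#' @export
build_smorf_db <- function(transcripts, species = "unknown", six_frame = TRUE,
                           min_aa = 10, max_aa = 150) {
  orfs <- find_orfs(transcripts, min_codons = min_aa, max_codons = max_aa,
                    both_strands = six_frame)
  df <- data.frame(id = orfs$orf_id, peptide = orfs$peptide,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$peptide), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, species = species, class = c("smorf_db", "data.frame"))
}

#' Construct an smORF database from peptides directly
#'
#' @param peptides Named (or unnamed) character vector of peptides, 10-150 AA.
#' @param species Species identifier.
#' @return A `smorf_db`.
#' @export
smorf_db <- function(peptides, species = "unknown") {
  ids <- names(peptides)
  if (is.null(ids))
    ids <- if (length(peptides)) paste0(species, "_", seq_along(peptides))
      else character(0)
  if (anyDuplicated(ids)) stop("smorf_db: duplicate ids")
  len <- nchar(peptides)
  if (any(len < 10 | len > 150))
    stop("smorf_db: peptides must be 10-150 AA")
  structure(data.frame(id = ids, peptide = unname(peptides),
                       stringsAsFactors = FALSE),
            species = species, class = c("smorf_db", "data.frame"))
}

# Smith-Waterman local alignment scores of one peptide against a set.
# BLOSUM62, affine gaps (open 11, extend 1), the classic protein-search
# parameterisation.
.sw_scores <- function(query, targets) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(targets),
    subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

.sw_align <- function(query, target) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(target),
    subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = 11, gapExtension = 1)
  list(query = as.character(Biostrings::alignedSubject(al)),
       target = as.character(Biostrings::alignedPattern(al)),
       score = BiocGenerics::score(al))
}

#' Forward search with reciprocal best-hit validation
#'
#' Ranks the target database against the query peptide by local-alignment
#' score (Smith-Waterman, BLOSUM62, affine gaps 11/1), keeping forward hits
#' scoring at least `score_floor` times the query's self-score. Each forward
#' hit, in rank order, is searched back against the query species' whole
#' ORFome: the hit is validated only when the original query is the top
#' reciprocal hit. The first validated hit is aligned, annotated for
#' conservation, and scored.
#'
#' @param query_id Identifier of the query peptide in `query_db`.
#' @param query_db `smorf_db` of the query species (whole ORFome).
#' @param target_db `smorf_db` of the target species.
#' @param score_floor Fraction of the query self-score a forward hit must
#'   reach (default 0.4).
#' @return A list (class `homology_hit`) with `query`, `species`, `target`,
#'   `forward_score`, `reciprocal_ok`, `alignment`, `annotation`, `identity`
#'   (percent identical columns over query length) and `genor_score`; or
#'   `NULL` when no validated hit exists.
#' @export
search_and_validate <- function(query_id, query_db, target_db,
                                score_floor = 0.4) {
  stopifnot(inherits(query_db, "smorf_db"), inherits(target_db, "smorf_db"))
  qi <- match(query_id, query_db$id)
  if (is.na(qi)) stop("search_and_validate: query not in query_db")
  query <- query_db$peptide[qi]
  if (nrow(target_db) == 0) return(NULL)
  self_score <- .sw_scores(query, query)
  fwd <- .sw_scores(query, target_db$peptide)
  ord <- order(fwd, decreasing = TRUE)
  ord <- ord[fwd[ord] >= score_floor * self_score]
  for (ti in ord) {
    rec <- .sw_scores(target_db$peptide[ti], query_db$peptide)
    top <- which(rec == max(rec))
    if (!(qi %in% top)) next                       # paralog trap: reject
    al <- .sw_align(query, target_db$peptide[ti])
    ann <- annotate_conservation(al$query, al$target)
    qlen <- nchar(query)
    chars_q <- strsplit(al$query, NULL)[[1]]
    chars_t <- strsplit(al$target, NULL)[[1]]
    ident <- 100 * sum(chars_q == chars_t & chars_q != "-") / qlen
    return(structure(list(
      query = query_id, species = attr(target_db, "species"),
      target = target_db$id[ti], forward_score = fwd[ti],
      reciprocal_ok = TRUE,
      alignment = list(query = al$query, target = al$target),
      annotation = ann, identity = ident,
      genor_score = genor_score(ann, qlen)), class = "homology_hit"))
  }
  NULL
}

#' Annotate per-column conservation of a pairwise peptide alignment
#'
#' Clustal-style annotation string: `*` for identical residues, `:` for
#' pairs scoring > 0.5 in the PAM250 matrix (strong biochemical similarity),
#' `.` for pairs within a Clustal weak-similarity group, and space otherwise
#' or at gap columns.
#'
#' @param aligned_query,aligned_target Equal-length aligned strings
#'   (gap `-`).
#' @return Annotation string over `{*, :, ., ' '}`.
#' @export
annotate_conservation <- function(aligned_query, aligned_target) {
  if (nchar(aligned_query) != nchar(aligned_target))
    stop("annotate_conservation: aligned strings must have equal length")
  data("PAM250", package = "Biostrings", envir = environment())
  a <- strsplit(aligned_query, NULL)[[1]]
  b <- strsplit(aligned_target, NULL)[[1]]
  ann <- vapply(seq_along(a), function(i) {
    x <- a[i]; y <- b[i]
    if (x == "-" || y == "-") return(" ")
    if (x == y) return("*")
    if (PAM250[x, y] > 0.5) return(":")
    in_weak <- any(vapply(.WEAK_GROUPS, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), logical(1)))
    if (in_weak) "." else " "
  }, character(1))
  paste(ann, collapse = "")
}

#' Conservation-weighted alignment score
#'
#' Fully conserved columns (`*`) weigh 100, strong similarities (`:`) 70,
#' weak similarities (`.`) 30; the weights are summed across alignment
#' positions and divided by the total query length, giving a score in
#' `[0, 100]` (100 = full-length perfect conservation).
#'
#' @param annotation Annotation string from [annotate_conservation()].
#' @param query_length Length of the (unaligned) query peptide (> 0).
#' @return Numeric score.
#' @export
genor_score <- function(annotation, query_length) {
  if (query_length <= 0) stop("genor_score: query_length must be > 0")
  ch <- strsplit(annotation, NULL)[[1]]
  (100 * sum(ch == "*") + 70 * sum(ch == ":") + 30 * sum(ch == ".")) /
    query_length
}

#' Conservation depth of a query across a species panel
#'
#' Counts the species (ordered nearest to most divergent) with a validated
#' reciprocal hit passing the identity and score thresholds, and reports the
#' most divergent such species.
#'
#' @param hits Named list of `homology_hit` (or NULL) per species, ordered
#'   from least to most divergent.
#' @param min_identity Percent-identity floor (default 50, exclusive).
#' @param min_score Score floor on the conservation-weighted score
#'   (default 0).
#' @return List with `n_species` and `deepest_species` (NA when none).
#' @export
conservation_depth <- function(hits, min_identity = 50, min_score = 0) {
  ok <- vapply(hits, function(h) {
    !is.null(h) && isTRUE(h$reciprocal_ok) &&
      h$identity > min_identity && h$genor_score >= min_score
  }, logical(1))
  list(n_species = sum(ok),
       deepest_species = if (any(ok)) names(hits)[max(which(ok))] else NA_character_)
}
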