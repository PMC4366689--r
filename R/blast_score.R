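#' Karlin-Altschul scoring parameters
#'
#' Reward/penalty scores for ungapped nucleotide alignment together with
#' the Karlin-Altschul constants used to convert raw scores to bit scores
#' and E-values. The defaults (+1/-2, lambda 1.28, K 0.46) are the standard
#' megablast parameterization; under them a perfect ungapped 104-nt match
#' scores 104 raw = 193 displayed bits.
#'
#' @param reward integer match reward (> 0).
#' @param penalty integer mismatch penalty (< 0).
#' @param lambda Karlin-Altschul lambda (> 0), in units of 1/score.
#' @param K Karlin-Altschul K (> 0), dimensionless.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(reward = 1L, penalty = -2L,
                           lambda = 1.28, K = 0.46) {
  reward <- as.integer(reward); penalty <- as.integer(penalty)
  if (!(reward > 0L && penalty < 0L)) stop("require reward > 0 > penalty")
  if (!(lambda > 0 && K > 0)) stop("lambda and K must be positive")
  structure(list(reward = reward, penalty = penalty,
                 lambda = lambda, K = K),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring: match ", sprintf("%+d", x$reward), ", mismatch ",
      sprintf("%+d", x$penalty), "; lambda = ", x$lambda, ", K = ", x$K,
      "\n", sep = "")
  invisible(x)
}

#' Best ungapped local alignment score
#'
#' Maximum, over all ungapped placements of the query against the subject
#' on both strands, of the maximal-scoring segment on each diagonal
#' (matches scored `reward`, mismatches `penalty`; positions involving a
#' gap or ambiguity code score as mismatches). The score is never negative:
#' the empty segment scores 0.
#'
#' @param query,subject nucleotide strings.
#' @param params a [scoring_params()].
#' @param both_strands also scan the reverse complement of the subject.
#' @return integer raw score.
#' @examples
#' best_ungapped_score(strrep("ACGT", 26), strrep("ACGT", 26))  # 104
#' @export
best_ungapped_score <- function(query, subject, params = scoring_params(),
                                both_strands = TRUE) {
  stopifnot(inherits(params, "scoring_params"))
  q <- strsplit(.norm_string(query), "", fixed = TRUE)[[1L]]
  s <- strsplit(.norm_string(subject), "", fixed = TRUE)[[1L]]
  if (length(q) == 0L || length(s) == 0L) stop("empty sequence")
  best <- .best_score_one_strand(q, s, params)
  if (both_strands) {
    src <- strsplit(.revcomp(paste(s, collapse = "")), "", fixed = TRUE)[[1L]]
    best <- max(best, .best_score_one_strand(q, src, params))
  }
  best
}

## Maximal-scoring segment over every diagonal of the ungapped dot-plot.
.best_score_one_strand <- function(q, s, params) {
  m <- length(q); n <- length(s)
  q_ok <- .is_state(q); s_ok <- .is_state(s)
  best <- 0L
  for (d in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(m, n - d)
    if (i0 > i1) next
    qi <- i0:i1
    si <- qi + d
    match <- q[qi] == s[si] & q_ok[qi] & s_ok[si]
    sc <- ifelse(match, params$reward, params$penalty)
    # max subarray (Kadane via prefix sums), floored at the empty segment
    cs <- cumsum(sc)
    seg <- max(cs - cummin(c(0, cs[-length(cs)])))
    if (seg > best) best <- as.integer(seg)
  }
  best
}

#' Bit score from a raw score
#'
#' `(lambda * raw - ln K) / ln 2`. The displayed score is the bit score
#' rounded half-away-from-zero to an integer, as score lists convention;
#' full precision is retained in the returned value.
#'
#' @param raw_score nonnegative raw score(s).
#' @param params a [scoring_params()].
#' @return numeric bit score(s); see [displayed_bits()] for the integer
#'   form.
#' @examples
#' bit_score(104)              # ~193.2
#' displayed_bits(104)         # 193
#' @export
bit_score <- function(raw_score, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"), all(raw_score >= 0))
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' @rdname bit_score
#' @export
displayed_bits <- function(raw_score, params = scoring_params()) {
  b <- bit_score(raw_score, params)
  as.integer(sign(b) * floor(abs(b) + 0.5))
}

#' E-value of a raw score
#'
#' `K * m * n * exp(-lambda * raw)` with `m` the query length and `n` the
#' total database length. No effective-length (edge) correction is applied.
#'
#' @param raw_score nonnegative raw score(s).
#' @param query_len query length (> 0).
#' @param db_len total database length (> 0).
#' @param params a [scoring_params()].
#' @return numeric E-value(s).
#' @export
evalue <- function(raw_score, query_len, db_len, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"),
            query_len > 0, db_len > 0, all(raw_score >= 0))
  params$K * query_len * db_len * exp(-params$lambda * raw_score)
}

#' Rank a sequence database against a query
#'
#' Scores every subject with [best_ungapped_score()], converts to bit
#' scores and E-values, and ranks by bit score (descending). Subjects with
#' equal *displayed* (integer) bit scores form a tie group; within a tie
#' group the order is a stable sort by subject id, so the ranking is
#' invariant to database order.
#'
#' @param query query string.
#' @param database a [labeled_alignment()] or path to a FASTA file with
#'   `species=` headers.
#' @param params a [scoring_params()].
#' @param both_strands scan both strands of each subject.
#' @return object of class `hit_ranking`: a data.frame with columns
#'   `subject_id`, `species`, `raw_score`, `bit_score`, `displayed_bits`,
#'   `evalue`, `tie_group`, `rank`, sorted by rank; attribute
#'   `tie_group_sizes` summarises per-group sizes and species composition.
#' @export
rank_database <- function(query, database, params = scoring_params(),
                          both_strands = TRUE) {
  if (is.character(database) && length(database) == 1L)
    database <- read_alignment_fasta(database)
  stopifnot(inherits(database, "labeled_alignment"))
  subjects <- alignment_strings(database)
  if (length(subjects) == 0L) stop("empty database")
  raw <- vapply(subjects, function(s)
    best_ungapped_score(query, s, params, both_strands), integer(1L))
  bits <- bit_score(raw, params)
  disp <- displayed_bits(raw, params)
  ev <- evalue(raw, nchar(.norm_string(query)),
               sum(nchar(subjects)), params)
  ord <- order(-bits, database$ids, method = "radix")
  df <- data.frame(subject_id = database$ids[ord],
                   species = database$species[ord],
                   raw_score = raw[ord],
                   bit_score = bits[ord],
                   displayed_bits = disp[ord],
                   evalue = ev[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  ## tie groups are runs of equal displayed bits in the sorted order
  df$tie_group <- with(rle(df$displayed_bits),
                       rep(seq_along(lengths), lengths))
  df$rank <- seq_len(nrow(df))
  sizes <- lapply(split(df, df$tie_group), function(g)
    list(displayed_bits = g$displayed_bits[1L], size = nrow(g),
         species = table(g$species)))
  structure(df, class = c("hit_ranking", "data.frame"),
            tie_group_sizes = sizes, params = params)
}

#' @export
print.hit_ranking <- function(x, n = 10L, ...) {
  cat("Hit ranking:", nrow(x), "subjects,",
      length(attr(x, "tie_group_sizes")), "tie group(s)\n")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Tie-group summary of a hit ranking
#' @param object a `hit_ranking`.
#' @param ... unused.
#' @return data.frame with one row per tie group: displayed bits, size and
#'   species composition.
#' @export
summary.hit_ranking <- function(object, ...) {
  sizes <- attr(object, "tie_group_sizes")
  do.call(rbind, lapply(names(sizes), function(g) {
    el <- sizes[[g]]
    data.frame(tie_group = as.integer(g),
               displayed_bits = el$displayed_bits, size = el$size,
               species = paste(sprintf("%s (%d)", names(el$species),
                                       el$species), collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Write a hit ranking as TSV
#' @param ranking a `hit_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
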