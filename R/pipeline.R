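#' Assemble a pipeline run configuration
#'
#' Collects everything one identification run needs. Sequence inputs may be
#' given as file paths (FASTA, species labels in `species=` header keys) or
#' as in-memory objects; the provenance block of the report echoes the
#' configuration either way.
#'
#' @param query query fragment(s): path to a FASTA file, a character vector
#'   of sequences, or a [labeled_alignment()].
#' @param reference reference gene sequence: FASTA path or a string.
#' @param database species database: FASTA path or a [labeled_alignment()].
#' @param min_identity minimum mapping identity (see [map_fragment()]).
#' @param params a [scoring_params()].
#' @param kmax largest diagnostic combination size searched.
#' @param mode assignment mode, `"site_wise"` or `"exact_haplotype"`.
#' @param tree run the NJ bootstrap tree check.
#' @param n_replicates bootstrap replicates for the tree check.
#' @param seed integer seed (bootstrap resampling; echoed everywhere).
#' @param output_dir if non-`NULL`, artifacts (TSV tables, JSON report,
#'   newick tree) are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(query, reference, database,
                       min_identity = 0.8,
                       params = scoring_params(),
                       kmax = 4L,
                       mode = c("site_wise", "exact_haplotype"),
                       tree = TRUE,
                       n_replicates = 1000L,
                       seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  for (p in c(query, reference, database)) {
    if (is.character(p) && length(p) == 1L && grepl("\\.(fa|fasta|fna)$", p)
        && !file.exists(p))
      stop("input file not found: ", p)
  }
  structure(list(query = query, reference = reference, database = database,
                 min_identity = min_identity, params = params,
                 kmax = as.integer(kmax), mode = mode, tree = tree,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a plain key=value file
#'
#' Recognised keys: `query`, `reference`, `database`, `min_identity`,
#' `reward`, `penalty`, `lambda`, `K`, `kmax`, `mode`, `tree`,
#' `n_replicates`, `seed`, `output_dir`. Lines starting with `#` and blank
#' lines are ignored. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path path to the config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1L)) < 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x)
    paste(x[-1L], collapse = "="), character(1L)))
  conf <- stats::setNames(as.list(vals), keys)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) return(p)
    cand <- file.path(dir, p)
    if (file.exists(cand)) cand else p
  }
  num <- function(k, d) if (is.null(conf[[k]])) d else as.numeric(conf[[k]])
  run_config(
    query = resolve(conf$query),
    reference = resolve(conf$reference),
    database = resolve(conf$database),
    min_identity = num("min_identity", 0.8),
    params = scoring_params(reward = num("reward", 1),
                            penalty = num("penalty", -2),
                            lambda = num("lambda", 1.28),
                            K = num("K", 0.46)),
    kmax = num("kmax", 4),
    mode = if (is.null(conf$mode)) "site_wise" else conf$mode,
    tree = if (is.null(conf$tree)) TRUE
           else toupper(conf$tree) %in% c("TRUE", "YES", "1"),
    n_replicates = num("n_replicates", 1000),
    seed = num("seed", 1),
    output_dir = conf$output_dir)
}

.load_queries <- function(query) {
  if (inherits(query, "labeled_alignment")) return(query)
  if (length(query) == 1L && file.exists(query))
    return(read_alignment_fasta(query))
  labeled_alignment(query, ids = paste0("query", seq_along(query)),
                    species = rep("QUERY", length(query)))
}

.load_reference <- function(reference) {
  if (length(reference) == 1L && file.exists(reference)) {
    ss <- Biostrings::readBStringSet(reference)
    return(stats::setNames(as.character(ss[1L]),
                           sub("\\s.*$", "", names(ss)[1L])))
  }
  stats::setNames(.norm_string(reference), "reference")
}

.load_database <- function(database) {
  if (inherits(database, "labeled_alignment")) return(database)
  read_alignment_fasta(database)
}

#' Run the full fragment-identification pipeline
#'
#' Executes, in order: fragment-to-reference mapping, per-site variability
#' tabulation, population aggregation analysis (single-site diagnostics,
#' combination search and per-query assignment), similarity ranking of the
#' database against each query, and the NJ bootstrap tree check. Stages
#' that cannot run on the given inputs (e.g. the diagnostic search with a
#' single-species database) are marked skipped with a reason rather than
#' failing the run.
#'
#' @param config a [run_config()].
#' @return object of class `identification_report`: list with elements
#'   `mapping`, `variability`, `paa` (diagnostics + verdicts), `blast`,
#'   `tree`, `skipped` (named reasons), and `provenance` (config echo,
#'   seed, package version). If `config$output_dir` is set, artifacts are
#'   written there (`mapping.tsv`, `variability.tsv`, `hits_<query>.tsv`,
#'   `verdicts.tsv`, `tree.nwk`, `report.json`, `summary.txt`).
#' @examples
#' fx <- build_bear_fixture()
#' parts <- split_queries(fx)
#' rf <- generate_reference_and_fragment(700, 451, 554, seed = 11)
#' db_frag <- parts$species
#' cfg <- run_config(query = parts$query, reference = rf$reference,
#'                   database = db_frag, tree = FALSE, seed = 1)
#' \donttest{rep <- run_identification(cfg)}
#' @export
run_identification <- function(config) {
  stopifnot(inherits(config, "run_config"))
  skipped <- list()
  queries <- .load_queries(config$query)
  reference <- .load_reference(config$reference)
  database <- .load_database(config$database)
  species <- unique(database$species[database$species != "QUERY"])

  ## 1. map the first query onto the reference (queries are identical in
  ##    the canonical use case; each is mapped and checked for agreement)
  qstrings <- alignment_strings(queries)
  mappings <- lapply(qstrings, function(q)
    map_fragment(q, reference[[1L]], config$min_identity,
                 reference_id = names(reference)))
  mapped <- vapply(mappings, function(m) isTRUE(m$mapped), logical(1L))
  mapping <- if (any(mapped)) mappings[[which(mapped)[1L]]] else NULL
  if (is.null(mapping))
    skipped$mapping <- "no query mapped above the identity threshold"

  ## 2. variability table of database + queries in the mapped frame
  frame <- if (!is.null(mapping) &&
               mapping$fragment_length == ncol(database$seq)) mapping
           else fragment_mapping(1L, ncol(database$seq))
  combined <- labeled_alignment(rbind(database$seq, queries$seq),
                                c(database$ids, queries$ids),
                                c(database$species, queries$species))
  variability <- tabulate_variability(combined, frame)

  ## 3. population aggregation analysis
  paa <- NULL
  profiles <- species_profiles(combined, frame)
  verdicts <- lapply(seq_along(queries$ids), function(i)
    assign_query(queries[i], profiles, frame, mode = config$mode))
  if (length(species) == 2L) {
    diagnostics <- diagnostic_combinations(profiles, species[1L], species[2L],
                                           kmax = config$kmax)
  } else {
    diagnostics <- NULL
    skipped$diagnostics <- paste0("pairwise diagnosis needs exactly 2 ",
                                  "species, found ", length(species))
  }
  paa <- list(profiles = profiles, diagnostics = diagnostics,
              verdicts = verdicts)

  ## 4. similarity ranking per query
  blast <- lapply(qstrings, function(q)
    rank_database(q, database, config$params))

  ## 5. NJ bootstrap tree check on the species database
  tree <- NULL
  if (isTRUE(config$tree)) {
    if (length(database$ids) >= 3L) {
      tree <- bootstrap_support(database, config$n_replicates, config$seed)
    } else {
      skipped$tree <- "tree check needs at least 3 database sequences"
    }
  } else skipped$tree <- "disabled in config"

  report <- structure(
    list(mapping = mapping, mappings = mappings, variability = variability,
         paa = paa, blast = blast, tree = tree, skipped = skipped,
         provenance = list(
           seed = config$seed,
           mode = config$mode,
           kmax = config$kmax,
           min_identity = config$min_identity,
           scoring = unclass(config$params),
           n_replicates = if (isTRUE(config$tree)) config$n_replicates else NULL,
           n_queries = length(queries$ids),
           database_species = as.list(table(database$species)),
           package_version = as.character(utils::packageVersion("fragdiag")))),
    class = "identification_report")
  if (!is.null(config$output_dir))
    write_report_artifacts(report, config$output_dir)
  report
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Fragment identification report\n")
  if (!is.null(x$mapping)) print(x$mapping)
  vp <- variable_positions(x$variability)
  cat("Variable positions: ",
      if (length(vp)) paste(vp, collapse = ", ") else "none", "\n", sep = "")
  if (!is.null(x$paa$diagnostics)) {
    d <- x$paa$diagnostics
    total <- length(d$single_site_diagnostics) +
      sum(lengths(d$combination_diagnostics))
    cat("Diagnostic characters/combinations (k <= ", d$kmax, "): ",
        total, "\n", sep = "")
  }
  for (v in x$paa$verdicts) print(v)
  for (qid in names(x$blast)) {
    top <- x$blast[[qid]][1L, ]
    cat("Best hit for '", qid, "': ", top$subject_id, " (", top$species,
        "), ", top$displayed_bits, " bits\n", sep = "")
  }
  if (!is.null(x$tree)) print(x$tree)
  for (stage in names(x$skipped))
    cat("[skipped] ", stage, ": ", x$skipped[[stage]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.identification_report <- function(object, ...) {
  verdicts <- do.call(rbind, lapply(object$paa$verdicts, function(v)
    data.frame(query_id = v$query_id, mode = v$mode,
               compatible_species = paste(v$compatible_species,
                                          collapse = ";"),
               status = v$status, stringsAsFactors = FALSE)))
  verdicts
}

#' Serialise a report to structured JSON
#'
#' Every number in the JSON comes from the stage objects; nothing is
#' recomputed. Deterministic for a fixed config and seed.
#'
#' @param report an `identification_report`.
#' @return a JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "identification_report"))
  vp <- variable_positions(report$variability)
  x <- list(
    provenance = report$provenance,
    mapping = if (!is.null(report$mapping)) {
      m <- report$mapping
      list(reference_id = m$reference_id, ref_start = m$ref_start,
           ref_end = m$ref_end, strand = m$strand, identity = m$identity,
           fragment_length = m$fragment_length)
    },
    variability = list(
      variable_positions = vp,
      counts = lapply(report$variability$counts, function(cnt)
        apply(cnt[, as.character(vp), drop = FALSE], 2L,
              function(col) as.list(col[col > 0L]), simplify = FALSE))),
    diagnostics = if (!is.null(report$paa$diagnostics)) {
      d <- report$paa$diagnostics
      list(single_site = d$single_site_diagnostics,
           combinations = lapply(d$combination_diagnostics, function(hits)
             lapply(hits, as.integer)),
           kmax = d$kmax)
    },
    verdicts = lapply(report$paa$verdicts, function(v)
      list(query_id = v$query_id, mode = v$mode,
           compatible_species = v$compatible_species, status = v$status)),
    blast = lapply(report$blast, function(h) {
      s <- summary(h)
      list(n_subjects = nrow(h),
           tie_groups = lapply(seq_len(nrow(s)), function(i)
             list(displayed_bits = s$displayed_bits[i], size = s$size[i],
                  species = s$species[i])))
    }),
    tree = if (!is.null(report$tree))
      list(n_replicates = report$tree$n_replicates,
           seed = report$tree$seed,
           n_splits = length(report$tree$splits),
           categories = as.list(table(report$tree$categories))),
    skipped = report$skipped)
  jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                   null = "null")
}

#' Write all report artifacts to a directory
#' @param report an `identification_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$mapping))
    write_mapping_tsv(report$mapping, file.path(dir, "mapping.tsv"))
  write_variability_tsv(report$variability, file.path(dir, "variability.tsv"))
  verdicts <- summary(report)
  utils::write.table(verdicts, file.path(dir, "verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (qid in names(report$blast))
    write_hits_tsv(report$blast[[qid]],
                   file.path(dir, paste0("hits_", qid, ".tsv")))
  if (!is.null(report$tree))
    write_supported_tree(report$tree, file.path(dir, "tree.nwk"))
  writeLines(report_to_json(report), file.path(dir, "report.json"))
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(dir)
}
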