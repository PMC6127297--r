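# Workflow driver: configuration handling and the end-to-end design run
# (partition -> amplicons -> tails -> entropy -> candidates ->
# specificity), with TSV outputs and a run log.

.CONFIG_DEFAULTS <- list(
  db = NULL, primers = NULL, out_dir = NULL,
  host_taxon = "Scleractinia", exclude_taxon = "Metazoa",
  tail_len = 40L, min_len = 20L, max_len = 29L, overlap_len = 10L,
  tm_tolerance = 5, consensus_min_freq = 0.9, minor_freq = 0.1,
  max_mismatch = 0L, min_coverage = 0.90, min_reads = 3L, alpha = 0.05,
  thresholds = seq(0.90, 0.99, by = 0.01), group_rank = 2L,
  allow_long = FALSE, seed = 1L
)

# Tiny polynomial hash of the resolved configuration, for output
# provenance (not cryptographic).
.config_hash <- function(config) {
  s <- paste(names(config),
             vapply(config, function(v) paste(format(v), collapse = ","),
                    character(1L)),
             sep = "=", collapse = ";")
  h <- 7
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Load a workflow configuration
#'
#' Reads a YAML (or JSON) configuration file, applies documented defaults
#' and validates ranges. Unknown keys are rejected. An empty file yields
#' the full default configuration.
#'
#' @param path Configuration file, or NULL for pure defaults.
#' @return Named list of resolved configuration values, with a
#'   `config_hash` attribute.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  config <- utils::modifyList(.CONFIG_DEFAULTS, user)
  if (config$max_len >= 30L && !isTRUE(config$allow_long)) {
    stop("max_len must be below 30 unless allow_long is set",
         call. = FALSE)
  }
  if (config$overlap_len < 1L || config$overlap_len > config$min_len) {
    stop("overlap_len out of range", call. = FALSE)
  }
  if (config$tm_tolerance < 0) stop("tm_tolerance must be non-negative",
                                    call. = FALSE)
  if (config$min_coverage < 0 || config$min_coverage > 1) {
    stop("min_coverage out of range", call. = FALSE)
  }
  if (config$alpha <= 0 || config$alpha > 1) {
    stop("alpha out of range", call. = FALSE)
  }
  attr(config, "config_hash") <- .config_hash(config)
  config
}

.write_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# blockprimr %s config_hash=%s",
                     as.character(utils::packageVersion("blockprimr")),
                     attr(config, "config_hash")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end blocking-primer design workflow
#'
#' Partitions the reference database into host and off-target sets,
#' restricts both to amplifiable sequences, designs and ranks blocking
#' primers, and scores the best candidate's per-group specificity. Writes
#' `candidates.tsv`, `report.tsv`, `entropy.tsv` (host and off-target
#' per-column entropies) and `run.log` to the output directory; every
#' table carries a header comment with the package version and a
#' configuration hash.
#'
#' @param config A configuration list from [load_config]; `db` (FASTA
#'   path), `primers` (primer-set JSON/YAML path) and `out_dir` must be
#'   set.
#' @param dry_run Print the resolved configuration and return without
#'   touching any file (default FALSE).
#' @return Invisibly, a list with the `blocking_design` object and the
#'   `specificity_report` of the best candidate.
#' @export
run_design_workflow <- function(config, dry_run = FALSE) {
  if (is.null(attr(config, "config_hash"))) {
    attr(config, "config_hash") <- .config_hash(config)
  }
  if (dry_run) {
    utils::str(config, give.head = FALSE)
    return(invisible(NULL))
  }
  for (f in c("db", "primers", "out_dir")) {
    if (is.null(config[[f]])) stop("configuration needs '", f, "'",
                                   call. = FALSE)
  }
  for (f in c("db", "primers")) {
    if (!file.exists(config[[f]])) {
      stop("input file not found: ", config[[f]], call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  cat("", file = logf)
  log("blockprimr %s", as.character(utils::packageVersion("blockprimr")))
  log("seed %d  config_hash %s", config$seed, attr(config, "config_hash"))
  for (key in names(config)) {
    log("config %s = %s", key, paste(format(config[[key]]), collapse = ","))
  }

  db <- read_fasta_db(config$db)
  primers <- read_primer_set(config$primers)
  log("stage partition: %d records", length(db))
  parts <- partition_host_offtarget(db, config$host_taxon,
                                    config$exclude_taxon)
  host <- filter_amplifiable(parts$host, primers,
                             max_mismatch = config$max_mismatch)
  off <- filter_amplifiable(parts$offtarget, primers,
                            max_mismatch = config$max_mismatch)
  log("stage amplicons: host %d, off-target %d", length(host), length(off))

  design <- design_blocking_primers(
    host, off, primers, tail_len = config$tail_len,
    max_mismatch = config$max_mismatch,
    criteria = blocking_criteria(max_mismatch = config$max_mismatch,
                                 overlap_len = config$overlap_len,
                                 amp_max_mismatch = config$max_mismatch),
    min_len = config$min_len, max_len = config$max_len,
    overlap_len = config$overlap_len,
    tm_tolerance = config$tm_tolerance,
    consensus_min_freq = config$consensus_min_freq,
    minor_freq = config$minor_freq, allow_long = config$allow_long)
  log("stage design: %d candidate(s), best %s",
      nrow(design$candidates), design$best$seq)

  report <- specificity_report(
    design$best$seq, primers, host, off, group_rank = config$group_rank,
    criteria = blocking_criteria(max_mismatch = config$max_mismatch,
                                 overlap_len = config$overlap_len,
                                 amp_max_mismatch = config$max_mismatch),
    host_label = config$host_taxon)
  log("stage specificity: %d group row(s)", nrow(report))

  .write_tsv(as.data.frame(design$candidates),
             file.path(config$out_dir, "candidates.tsv"), config)
  rep_df <- as.data.frame(report)
  rep_df$percent_blocked <- round(100 * rep_df$fraction_blocked, 1)
  .write_tsv(rep_df, file.path(config$out_dir, "report.tsv"), config)
  ent <- data.frame(position = seq_along(design$host_entropy$H),
                    H_host = design$host_entropy$H,
                    H_offtarget = if (!is.null(design$offtarget_entropy))
                      design$offtarget_entropy$H else NA_real_)
  .write_tsv(ent, file.path(config$out_dir, "entropy.tsv"), config)
  log("done")
  invisible(list(design = design, report = report))
}
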