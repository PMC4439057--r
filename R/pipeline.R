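# High-level workflows binding the stages together. Each pipeline_*
# function takes a plain config list (mirroring a YAML config file),
# writes TSV/Newick outputs under config$out_dir, logs a reproducibility
# line to stderr, and returns its results invisibly. The thin CLI script
# in inst/cli/cladistinct.R dispatches to these.
#
# Default thresholds, kept in one place: 25% burn-in, 0.70 consensus
# display threshold, 0.05 ASDSF and 1.01 PSRF convergence rules, 0.01
# SD display flag, 0.10 ASDSF minimum split frequency.

pipeline_defaults <- list(burnin = 0.25, consensus_threshold = 0.70,
                          asdsf_limit = 0.05, psrf_limit = 1.01,
                          sd_flag = 0.01, asdsf_min_freq = 0.10)

pipeline_log <- function(cmd, config) {
  message(sprintf("[cladistinct %s] %s | seed=%s | %s",
                  as.character(utils::packageVersion("cladistinct")),
                  cmd, config$seed %||% "NA",
                  paste(names(config), collapse = ",")))
}

apply_defaults <- function(config) {
  for (nm in names(pipeline_defaults))
    if (is.null(config[[nm]])) config[[nm]] <- pipeline_defaults[[nm]]
  if (is.null(config$out_dir)) config$out_dir <- "."
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  config
}

load_sample <- function(config) {
  ts <- if (!is.null(config[["sample"]])) config[["sample"]]
        else read_tree_sample(config$tree_files)
  apply_burnin(ts, config$burnin)
}

#' Summarize a posterior tree sample
#'
#' Applies burn-in, writes the majority-rule consensus (Newick, split
#' frequencies as node labels), the clade-support table (posterior
#' probabilities in % units with across-run SD flagged at the display
#' threshold), and convergence diagnostics (ASDSF; PSRF per scalar
#' parameter when trace files are given). With `strict = TRUE` an error
#' is raised when ASDSF meets or exceeds its limit.
#'
#' @param config List: `tree_files` (or a prebuilt `sample`),
#'   optional `trace_files`, `burnin`, `consensus_threshold`,
#'   `asdsf_min_freq`, `sd_flag`, `strict`, `out_dir`.
#' @return Invisible list: `consensus`, `support`, `asdsf`, `psrf`.
#' @export
pipeline_summarize <- function(config) {
  config <- apply_defaults(config)
  pipeline_log("summarize", config)
  ts <- load_sample(config)
  support <- clade_support(ts, sd_flag = config$sd_flag)
  cons <- majority_rule_consensus(do.call(c, lapply(ts$runs, as.list)),
                                  threshold = config$consensus_threshold)
  a <- if (length(ts$runs) >= 2L) asdsf(ts, config$asdsf_min_freq) else NA_real_
  ps <- NULL
  if (!is.null(config$trace_files)) {
    traces <- read_trace(config$trace_files)
    params <- setdiff(names(traces[[1]]), c("Gen", "gen", "Generation"))
    ps <- vapply(params, function(p) psrf(traces, p), 1)
  }
  rep_df <- support
  for (col in grep("^run|^mean_pp$|^sd_pp$", names(rep_df), value = TRUE))
    rep_df[[col]] <- 100 * rep_df[[col]]  # percent units
  write_report(rep_df, file.path(config$out_dir, "clade_support.tsv"))
  ape::write.tree(cons, file.path(config$out_dir, "consensus.nwk"))
  diag_df <- data.frame(statistic = "asdsf", value = a)
  if (!is.null(ps))
    diag_df <- rbind(diag_df, data.frame(statistic = paste0("psrf_", names(ps)),
                                         value = unname(ps)))
  write_report(diag_df, file.path(config$out_dir, "diagnostics.tsv"))
  if (isTRUE(config$strict) && !is.na(a) && a >= config$asdsf_limit)
    stop(sprintf("ASDSF %.4f >= %.2f: runs not converged", a,
                 config$asdsf_limit))
  invisible(list(consensus = cons, support = support, asdsf = a, psrf = ps))
}

#' Test monophyly hypotheses on a tree sample
#'
#' Estimates the posterior probability of each named constraint
#' (required clade + floating taxa) as its frequency in the pooled
#' post-burn-in sample, with Monte-Carlo error; zero-count constraints
#' are reported as "< 1/(N+1)".
#'
#' @param config List: `tree_files`/`sample`, `burnin`, `constraints`
#'   (named list, each with `required` and optional `floating`),
#'   `out_dir`.
#' @return Invisible data frame of per-constraint results.
#' @export
pipeline_hypothesis <- function(config) {
  config <- apply_defaults(config)
  pipeline_log("hypothesis", config)
  ts <- load_sample(config)
  if (!length(config$constraints)) stop("no constraints defined")
  rows <- lapply(names(config$constraints), function(nm) {
    cc <- config$constraints[[nm]]
    con <- monophyly_constraint(cc$required, cc$floating %||% character(0))
    h <- hypothesis_posterior(ts, con)
    data.frame(hypothesis = nm, prob = h$prob, se = h$se,
               n_trees = h$n_trees, n_satisfied = h$n_satisfied,
               report = h$format, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write_report(out, file.path(config$out_dir, "hypotheses.tsv"))
  invisible(out)
}

#' Ancestral states and trait indices over a tree sample
#'
#' Reconstructs marginal ancestral-state posterior probabilities for
#' each named clade over the post-burn-in sample, then computes the
#' distinctness and uniqueness indices against the other clades plus
#' the ancestor node and writes ranked top-`top_n` diagnostic reports
#' (values at two decimals). With `pp_file` set, the reconstruction is
#' skipped and indices are computed straight from a supplied PP table.
#'
#' @param config List: `tree_files`/`sample` + `matrix_file` (or
#'   `matrix`), `clades` (named list of taxon vectors including the
#'   ancestor clade), `ancestor` (its name), `alpha`, `ncat`,
#'   `conditioning`, `top_n` (default 6), `out_dir`; or `pp_file`.
#' @return Invisible list: `pp` and `indices`.
#' @export
pipeline_ancestral_indices <- function(config) {
  config <- apply_defaults(config)
  pipeline_log("ancestral_indices", config)
  if (!is.null(config$pp_file)) {
    pp <- read_pp_table(config$pp_file)
  } else {
    ts <- load_sample(config)
    cm <- if (!is.null(config[["matrix"]])) config[["matrix"]]
          else read_character_matrix(config$matrix_file)
    pp <- ancestral_pp_over_sample(
      ts, cm, config$clades,
      alpha = config$alpha %||% Inf, ncat = config$ncat %||% 4L,
      conditioning = config$conditioning %||% "none")
    write_pp_table(pp, file.path(config$out_dir, "ancestral_pp.tsv"))
  }
  idx <- trait_indices(pp, ancestor = config$ancestor %||% "ancestor")
  write_report(idx, file.path(config$out_dir, "indices.tsv"))
  top_n <- config$top_n %||% 6L
  write_report(format_index_report(idx, "distinctness", top_n),
               file.path(config$out_dir, "report_distinctness.tsv"))
  write_report(format_index_report(idx, "uniqueness", top_n),
               file.path(config$out_dir, "report_uniqueness.tsv"))
  invisible(list(pp = pp, indices = idx))
}

#' GC composition report
#'
#' @param config List: `alignment_file` (or `alignment`), `groups`
#'   (named list of taxon vectors), optional `partition` and `position`,
#'   `out_dir`.
#' @return Invisible [group_gc_summary()] result.
#' @export
pipeline_gc <- function(config) {
  config <- apply_defaults(config)
  pipeline_log("gc", config)
  aln <- if (!is.null(config[["alignment"]])) config[["alignment"]]
         else read_alignment(config$alignment_file)
  res <- group_gc_summary(aln, config$groups,
                          partition = config[["partition"]],
                          position = config[["position"]])
  write_report(res$taxa, file.path(config$out_dir, "gc_taxa.tsv"))
  write_report(res$groups, file.path(config$out_dir, "gc_groups.tsv"))
  invisible(res)
}

#' Generate a complete synthetic fixture bundle
#'
#' Simulates the true tree, character matrix, DNA alignment and
#' pseudo-posterior runs for a recipe and writes them (plus truth
#' tables) under one directory in the same formats the readers consume.
#'
#' @param config List: `recipe` (a [simulation_recipe()] or argument
#'   list for one), `out_dir`.
#' @return Invisible list of the simulated objects.
#' @export
pipeline_simulate <- function(config) {
  config <- apply_defaults(config)
  recipe <- config$recipe
  if (!inherits(recipe, "simulation_recipe")) {
    recipe <- recipe %||% list()
    if (!is.null(config$seed) && is.null(recipe$seed))
      recipe$seed <- config$seed  # --seed flows into a default recipe
    recipe <- do.call(simulation_recipe, recipe)
  }
  config$seed <- recipe$seed
  pipeline_log("simulate", config)
  sim <- simulate_tree(recipe)
  mk <- simulate_mk_matrix(sim$tree, recipe, sim$clades)
  aln <- simulate_dna(sim$tree, recipe, sim$clades)
  post <- simulate_posterior_sample(sim$tree, recipe,
                                    outgroup = sim$outgroup)
  od <- config$out_dir
  ape::write.tree(sim$tree, file.path(od, "true_tree.nwk"))
  write_character_matrix(mk$matrix, file.path(od, "characters.nex"))
  write_alignment(aln, file.path(od, "alignment.nex"), format = "nexus")
  write_tree_sample(post$sample,
                    file.path(od, sprintf("run%d.t",
                                          seq_along(post$sample$runs))))
  write_report(post$truth, file.path(od, "split_truth.tsv"))
  anc <- data.frame(node = rownames(mk$truth$ancestral),
                    mk$truth$ancestral, check.names = FALSE)
  write_report(anc, file.path(od, "ancestral_truth.tsv"))
  clade_df <- data.frame(
    clade = rep(names(sim$clades), lengths(sim$clades)),
    taxon = unlist(sim$clades), stringsAsFactors = FALSE)
  write_report(clade_df, file.path(od, "clades.tsv"))
  invisible(list(tree = sim$tree, clades = sim$clades,
                 outgroup = sim$outgroup, matrix = mk$matrix,
                 truth = mk$truth, alignment = aln, posterior = post))
}
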