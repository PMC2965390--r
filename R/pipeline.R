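#' Default configuration for the end-to-end synthetic run
#'
#' Returns the flat, sectioned configuration consumed by
#' [run_full_synthetic()]. The defaults encode the study conditions the
#' synthetic pipeline emulates: structure descriptors at a 4.5 A contact
#' cutoff with sequence separation >= 2 and a 16% burial threshold;
#' paralog thresholds >40% identity, >=80% coverage, >80% expression
#' consistency over 466 pseudo-experiments; a gene table whose rank
#' correlations mirror the expression associations (expression-Ka -0.45,
#' Ka-Ks +0.66, expression-solubility +0.27, expression-charged +0.28,
#' expression-Ks -0.50); and triplicate growth curves sampled every 45
#' minutes.
#'
#' @param seed master seed; every stage draws from a stream derived from
#'   it.
#' @export
default_pipeline_config <- function(seed = 1L) {
  vars <- c("expression", "Ka", "Ks", "solubility", "frac_charged")
  targets <- diag(1, 5)
  dimnames(targets) <- list(vars, vars)
  targets["expression", "Ka"] <- targets["Ka", "expression"] <- -0.45
  targets["expression", "Ks"] <- targets["Ks", "expression"] <- -0.50
  targets["Ka", "Ks"] <- targets["Ks", "Ka"] <- 0.66
  targets["expression", "solubility"] <-
    targets["solubility", "expression"] <- 0.27
  targets["expression", "frac_charged"] <-
    targets["frac_charged", "expression"] <- 0.28
  list(
    seed = as.integer(seed),
    structures = list(
      kinds = c("extended", "helix", "hairpin", "cluster"),
      length = 30L, cutoff = 4.5, min_separation = 2L,
      burial_threshold = 0.16, probe_radius = 1.4, n_sphere_points = 960L
    ),
    evolution = list(
      n_codons = 300L, expected_syn_subs = 0.3, omega = 0.2,
      min_identity = 0.40, min_coverage = 0.80, min_consistency = 0.80,
      paralog_identity = 0.5, paralog_consistency = 0.9,
      n_experiments = 466L
    ),
    gene_table = list(
      n_genes = 2000L,
      targets = targets,
      marginals = c(expression = "lognormal", Ka = "beta", Ks = "beta",
                    solubility = "uniform", frac_charged = "beta"),
      pairs = list(
        list(x = "expression", y = "Ka"),
        list(x = "Ka", y = "Ks"),
        list(x = "expression", y = "solubility"),
        list(x = "expression", y = "frac_charged"),
        list(x = "expression", y = "Ka", control = "Ks"),
        list(x = "expression", y = "Ks", control = "Ka")
      ),
      window = 200L
    ),
    growth = list(
      rates = c(induced = 0.519, uninduced = 0.6),
      od0 = 0.05, times = seq(0, 5.25, by = 0.75), noise_sd = 0.01,
      replicates = 3L, reference = "uninduced"
    )
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end to end with known ground truth: simulate toy
#' structures, coding pairs, a correlated gene table, a paralog family
#' and growth curves; compute structure descriptors; estimate Ka/Ks;
#' filter paralogs by identity, coverage and expression consistency; run
#' the association battery; and estimate growth rates and relative costs.
#' All stage outputs are written as TSV/PDB/FASTA under `out_dir` with
#' fixed numeric formatting, so a repeated run with the same config is
#' byte-identical.
#'
#' @param config configuration list from [default_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return object of class `run_report`: per-stage record counts,
#'   parameter echo, package version and the list of method deviations
#'   (the Ka/Ks stage stamps its counting-method estimator).
#' @export
run_full_synthetic <- function(config = default_pipeline_config(),
                               out_dir = tempfile("clockcost_run_")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  stages <- list()

  ## stage 1: structures -> descriptors
  sc <- config$structures
  desc_rows <- list()
  for (k in seq_along(sc$kinds)) {
    kind <- sc$kinds[k]
    fx <- make_structure(kind, length = sc$length, seed = seed + k,
                         cutoff = sc$cutoff,
                         min_separation = sc$min_separation)
    write_pdb(fx$structure, file.path(out_dir, paste0(kind, ".pdb")))
    row <- structure_descriptors(
      fx$structure, cutoff = sc$cutoff,
      min_separation = sc$min_separation,
      burial_threshold = sc$burial_threshold,
      probe_radius = sc$probe_radius,
      n_sphere_points = sc$n_sphere_points
    )
    desc_rows[[kind]] <- cbind(id = kind, row)
  }
  descriptors <- do.call(rbind, desc_rows)
  write_tsv_fixed(descriptors, file.path(out_dir, "descriptors.tsv"),
                  comment = run_header(config, "structure descriptors"))
  stages$structure_descriptors <- list(parsed = length(sc$kinds),
                                       retained = nrow(descriptors))

  ## stage 2: coding pair -> Ka/Ks
  ev <- config$evolution
  pair <- simulate_coding_pair(ev$n_codons, ev$expected_syn_subs,
                               ev$omega, seed = seed + 11L)
  write_fasta(c(ancestor = pair$cds_ancestor,
                descendant = pair$cds_descendant),
              file.path(out_dir, "coding_pair.fna"))
  prot_a <- paste(translate_codons(split_codons(pair$cds_ancestor)),
                  collapse = "")
  prot_b <- paste(translate_codons(split_codons(pair$cds_descendant)),
                  collapse = "")
  aln <- global_align(prot_a, prot_b)
  kk <- nei_gojobori(backtranslate_alignment(aln, pair$cds_ancestor,
                                             pair$cds_descendant))
  kaks_df <- data.frame(
    id_a = "ancestor", id_b = "descendant", identity = aln$identity,
    S_sites = kk$S_sites, N_sites = kk$N_sites, Sd = kk$Sd, Nd = kk$Nd,
    Ka = kk$Ka, Ks = kk$Ks,
    Ka_Ks = if (kk$Ks > 0) kk$Ka / kk$Ks else NA_real_,
    method = kk$method, stringsAsFactors = FALSE
  )
  write_tsv_fixed(kaks_df, file.path(out_dir, "kaks.tsv"),
                  comment = run_header(config, "Ka/Ks (NG86+JC)"))
  stages$kaks <- list(parsed = 1L, retained = nrow(kaks_df),
                      true_syn = pair$n_syn, true_nonsyn = pair$n_nonsyn)

  ## stage 3: paralog family -> identity/coverage/consistency filters
  fam <- simulate_paralog_family(ev$paralog_identity, ev$n_experiments,
                                 ev$paralog_consistency, seed = seed + 17L)
  write_fasta(fam$proteins, file.path(out_dir, "paralogs.faa"))
  expr_df <- data.frame(gene = rownames(fam$expression),
                        fam$expression, check.names = FALSE)
  write_tsv_fixed(expr_df, file.path(out_dir, "paralog_expression.tsv"))
  cand <- find_paralogs(fam$proteins, min_identity = ev$min_identity,
                        min_coverage = ev$min_coverage)
  retained <- 0L
  paralog_rows <- list()
  for (i in seq_len(nrow(cand))) {
    cons <- expression_consistency(cand[i, ], fam$expression,
                                   min_consistency = ev$min_consistency)
    paralog_rows[[i]] <- data.frame(
      cand[i, ], consistency = cons$consistency,
      high_expr_member = cons$high_expr_member,
      retained = cons$retained, stringsAsFactors = FALSE
    )
    retained <- retained + as.integer(cons$retained)
  }
  paralogs <- if (length(paralog_rows) > 0) do.call(rbind, paralog_rows)
              else cand
  write_tsv_fixed(paralogs, file.path(out_dir, "paralog_pairs.tsv"),
                  comment = run_header(config, "paralog filter"))
  stages$paralogs <- list(parsed = 1L, candidates = nrow(cand),
                          retained = retained)

  ## stage 4: gene table -> association battery
  gt <- config$gene_table
  table <- simulate_correlated_gene_table(gt$n_genes, gt$targets,
                                          gt$marginals, seed = seed + 23L)
  write_tsv_fixed(table, file.path(out_dir, "gene_table.tsv"))
  assoc <- run_association_suite(table, gt$pairs, seed = seed + 29L)
  write_tsv_fixed(assoc, file.path(out_dir, "associations.tsv"),
                  comment = run_header(config, "rank associations"))
  trend <- moving_average_trend(log(table$expression), table$Ka,
                                window = gt$window)
  write_tsv_fixed(trend, file.path(out_dir, "trend_expression_Ka.tsv"))
  stages$associations <- list(parsed = nrow(table), retained = nrow(assoc))

  ## stage 5: growth curves -> rates, costs, comparisons
  gr <- config$growth
  rate_rows <- list()
  curve_rows <- list()
  rep_seed <- seed + 31L
  for (s in names(gr$rates)) {
    for (r in seq_len(gr$replicates)) {
      rep_seed <- rep_seed + 1L
      curve <- simulate_growth_curve(gr$rates[[s]], gr$od0, gr$times,
                                     gr$noise_sd, seed = rep_seed)
      est <- estimate_growth_rate(curve)
      rate_rows[[paste(s, r)]] <- data.frame(
        strain = s, replicate = r, rate = est$rate, rate_se = est$rate_se,
        r_squared = est$r_squared, stringsAsFactors = FALSE
      )
      curve_rows[[paste(s, r)]] <- data.frame(
        strain = s, replicate = r, curve, stringsAsFactors = FALSE
      )
    }
  }
  rates <- do.call(rbind, rate_rows)
  write_tsv_fixed(do.call(rbind, curve_rows),
                  file.path(out_dir, "growth_curves.tsv"))
  comp <- compare_conditions(rates[, c("strain", "rate")],
                             reference = gr$reference)
  write_tsv_fixed(rates, file.path(out_dir, "growth_rates.tsv"),
                  comment = run_header(config, "growth rates"))
  write_tsv_fixed(comp$summary, file.path(out_dir, "growth_summary.tsv"))
  write_tsv_fixed(comp$tests, file.path(out_dir, "growth_tests.tsv"))
  stages$growth <- list(parsed = nrow(rates), retained = nrow(comp$summary))

  report <- structure(
    list(
      stages = stages,
      config = config,
      version = as.character(utils::packageVersion("clockcost")),
      deviations = c(
        "Ka/Ks estimated by Nei-Gojobori (1986) counting with Jukes-Cantor correction, not codon-model maximum likelihood",
        "solvent accessibility from in-package Shrake-Rupley, not DSSP"
      ),
      out_dir = out_dir
    ),
    class = "run_report"
  )
  saveRDS_free_report(report, file.path(out_dir, "run_report.tsv"))
  report
}

#' @noRd
run_header <- function(config, stage) {
  sprintf("clockcost %s | stage: %s | seed: %d",
          as.character(utils::packageVersion("clockcost")), stage,
          config$seed)
}

#' Plain-text run report (no binary serialization)
#' @noRd
saveRDS_free_report <- function(report, path) {
  lines <- c(
    paste0("# clockcost run report v", report$version),
    paste0("# seed\t", report$config$seed),
    paste0("# deviation\t", report$deviations),
    "stage\tkey\tvalue"
  )
  for (s in names(report$stages)) {
    st <- report$stages[[s]]
    lines <- c(lines, paste(s, names(st), unlist(st), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("clockcost run report (v", x$version, "), seed ", x$config$seed,
      "\n", sep = "")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-22s %s\n", s,
                paste(names(st), unlist(st), sep = "=", collapse = ", ")))
  }
  cat("deviations:\n")
  cat(paste0("  - ", x$deviations, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate pipeline input files
#'
#' Diagnostics-only format checks: FASTA files must parse and have unique
#' ids; PDB files must contain ATOM records with well-formed coordinate
#' fields; TSV tables must parse with at least one row; when both an
#' expression table (with a `gene` first column) and a FASTA file are
#' given, expression ids missing from the sequence set are reported.
#' Never throws on bad content — every problem becomes a diagnostic row.
#'
#' @param paths named list/vector of file paths; names choose the check
#'   by extension-independent role matching: `pdb*`, `fasta*`/`pep*`/
#'   `cds*`, `expr*`, anything else is checked as generic TSV.
#' @return data.frame with columns `file`, `role`, `status`, `detail`.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  note <- function(file, role, status, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, role = role, status = status, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  fasta_ids <- character(0)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) {
      note(p, nm, "error", "file not found")
      next
    }
    if (grepl("^pdb", nm)) {
      res <- tryCatch({
        st <- parse_structure(p)
        note(p, nm, "ok", paste0(n_residues(st), " residues, ",
                                 nrow(st$atoms), " atoms"))
      }, error = function(e) note(p, nm, "error", conditionMessage(e)))
    } else if (grepl("^(fasta|pep|cds)", nm)) {
      res <- tryCatch({
        seqs <- read_fasta(p)
        fasta_ids <- c(fasta_ids, names(seqs))
        if (anyDuplicated(names(seqs))) {
          note(p, nm, "error", "duplicate sequence ids")
        } else {
          note(p, nm, "ok", paste0(length(seqs), " sequences"))
        }
      }, error = function(e) note(p, nm, "error", conditionMessage(e)))
    } else {
      res <- tryCatch({
        df <- read_tsv_plain(p)
        if (nrow(df) == 0L) {
          note(p, nm, "error", "no data rows")
        } else {
          note(p, nm, "ok", paste0(nrow(df), " rows x ", ncol(df),
                                   " columns"))
        }
        if (grepl("^expr", nm) && length(fasta_ids) > 0) {
          missing <- setdiff(df[[1]], fasta_ids)
          if (length(missing) > 0) {
            note(p, nm, "warning",
                 paste0("ids absent from sequence set: ",
                        paste(missing, collapse = ", ")))
          }
        }
      }, error = function(e) note(p, nm, "error", conditionMessage(e)))
    }
  }
  do.call(rbind, rows)
}
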