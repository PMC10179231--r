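#' Run the full MEC-GWAS pipeline
#'
#' Chains the analysis end to end: pharmacokinetic simulation of each dosing
#' history, MEC extraction and log transform, clinical covariate screening,
#' the staged association scan under the requested genetic models, LD
#' pruning and FDR q-values, and QQ-plot data. A machine-readable run report
#' captures the seed, thresholds, and subject/SNP accounting at every
#' filter, so a run is fully reproducible from (inputs, config).
#'
#' @param geno A [genotype_matrix()].
#' @param histories Named list of [dosing_history()] objects.
#' @param covars Covariate table (data frame with `subject_id`).
#' @param params A [pk_params()] object.
#' @param phenotype Which MEC phenotype to analyse:
#'   `list(site = "plasma"|"effect", window_h = 6|12|24)`.
#' @param stages Number of stages (subjects split contiguously in input
#'   order into near-equal stages).
#' @param alpha,prune_r2,q_threshold Design thresholds.
#' @param models Genetic models to run.
#' @param covariate_policy `"screen"` (use variables passing the clinical
#'   screen at p < 0.05), `"all"`, or `"none"`.
#' @param out_dir Optional directory; when given, association TSV, phenotype
#'   CSV, QQ TSV and a JSON-like run report are written there.
#' @return A list of class `mecgwas_run`: `assoc` (stacked association
#'   table over models), `phenotypes`, `screen`, `qq`, `report`.
#' @export
run_pipeline <- function(geno, histories, covars, params,
                         phenotype = list(site = "effect", window_h = 12),
                         stages = 3, alpha = 0.05, prune_r2 = 0.8,
                         q_threshold = 0.05,
                         models = c("additive", "dominant", "recessive"),
                         covariate_policy = c("screen", "all", "none"),
                         out_dir = NULL) {
  covariate_policy <- match.arg(covariate_policy)
  pheno_tab <- mec_phenotype_table(histories, params)
  col <- sprintf("log_mec_%s_0_%dh",
                 ifelse(phenotype$site == "plasma", "plasma", "effect"),
                 phenotype$window_h)
  if (!col %in% names(pheno_tab)) stop("run_pipeline: unknown phenotype ", col)
  y <- stats::setNames(pheno_tab[[col]], pheno_tab$subject_id)

  Xall <- as_covariate_matrix(covars)
  common <- intersect(names(y)[!is.na(y)], rownames(Xall))
  common <- intersect(common, geno$subjects$subject_id)
  screen <- covariate_screen(y[common], Xall[common, , drop = FALSE])
  use_vars <- switch(covariate_policy,
                     screen = screen$variable[screen$selected],
                     all = colnames(Xall),
                     none = character())
  Xuse <- if (length(use_vars)) Xall[, use_vars, drop = FALSE] else NULL

  plan <- stage_plan(common, alpha = alpha, prune_r2 = prune_r2,
                     q_threshold = q_threshold,
                     sizes = .near_equal_sizes(length(common), stages))
  assoc <- do.call(rbind, lapply(models, function(mod) {
    staged_gwas(geno, y, Xuse, plan, model = mod)
  }))
  qq <- qq_data(assoc$stage1_p[!is.na(assoc$stage1_p) & assoc$model == models[1]])

  report <- list(
    n_subjects_input = length(histories),
    n_subjects_with_phenotype = sum(!is.na(y)),
    n_subjects_analyzed = length(common),
    stage_sizes = plan$sizes,
    n_snps = ncol(geno$calls),
    phenotype = col,
    covariates_used = use_vars,
    thresholds = list(alpha = alpha, prune_r2 = prune_r2,
                      q_threshold = q_threshold),
    n_survivors = stats::setNames(
      vapply(models, function(mod)
        sum(assoc$survived_stage[assoc$model == mod] == stages), integer(1)),
      models),
    n_significant = stats::setNames(
      vapply(models, function(mod)
        sum(assoc$significant[assoc$model == mod]), integer(1)),
      models))

  out <- structure(list(assoc = assoc, phenotypes = pheno_tab,
                        screen = screen, qq = qq, report = report),
                   class = "mecgwas_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_assoc_tsv(assoc, file.path(out_dir, "association.tsv"))
    write_phenotypes_csv(pheno_tab, file.path(out_dir, "phenotypes.csv"))
    utils::write.table(qq, file.path(out_dir, "qq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(.report_json(report), file.path(out_dir, "run_report.json"))
  }
  out
}

.near_equal_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  sizes
}

# minimal JSON serializer for the flat run report (avoids a hard dependency)
.report_json <- function(x, indent = "") {
  enc <- function(v) {
    if (is.list(v)) return(.report_json(v, paste0(indent, "  ")))
    if (length(v) == 0) return("[]")
    s <- if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15)
    if (length(v) > 1 || !is.null(names(v))) paste0("[", paste(s, collapse = ", "), "]") else s
  }
  body <- vapply(names(x), function(k) {
    sprintf('%s  "%s": %s', indent, k, enc(x[[k]]))
  }, character(1))
  paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}")
}

#' Write an association table as TSV
#' @param assoc An `assoc_table` from [staged_gwas()] (or several stacked).
#' @param path Output TSV.
#' @export
write_assoc_tsv <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.mecgwas_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("MEC-GWAS run: %d/%d subjects analyzed, %d SNPs, phenotype %s\n",
              r$n_subjects_analyzed, r$n_subjects_input, r$n_snps, r$phenotype))
  cat("  covariates:", if (length(r$covariates_used))
    paste(r$covariates_used, collapse = ", ") else "(none)", "\n")
  for (mod in names(r$n_survivors))
    cat(sprintf("  %s: %d final-stage survivor(s), %d genome-wide significant\n",
                mod, r$n_survivors[[mod]], r$n_significant[[mod]]))
  invisible(x)
}
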