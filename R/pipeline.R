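#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's \code{extdata} (empty to list).
#' @return Full path.
#' @export
heliomod_example <- function(file = "") {
  if (!nzchar(file))
    return(dir(system.file("extdata", package = "heliomod")))
  path <- system.file("extdata", file, package = "heliomod")
  if (!nzchar(path)) stop("no packaged file named '", file, "'")
  path
}

#' Read the packaged binding-thermodynamics reference table
#'
#' Published mean thermodynamic parameters (Kd in uM; dH, -TdS, dG in
#' kcal/mol at 25 C) for the heliorhodopsin variants titrated against the
#' transporter constructs; rows without calculable parameters carry NA.
#'
#' @return data.frame.
#' @export
read_thermo_table <- function() {
  utils::read.table(heliomod_example("itc_thermo_params.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Read the packaged ATPase kinetic-parameter reference table
#'
#' Published mean Michaelis-Menten parameters (Vmax uM/min, Km mM, kcat s^-1,
#' kcat/Km M^-1 s^-1 at 1 uM enzyme) per transporter/heliorhodopsin/light
#' condition.
#'
#' @return data.frame.
#' @export
read_kinetics_table <- function() {
  utils::read.table(heliomod_example("atpase_kinetics_params.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Thermodynamic closure report for a binding-parameter table
#'
#' Per row checks (at printed precision) that (1) dH + (-TdS) equals dG and
#' (2) R T ln(Kd) reproduces dG. Both checks allow half of the table's last
#' printed digit (0.05 kcal/mol) on top of the stated tolerance, since the
#' table stores rounded replicate means. Rows with non-numeric cells are
#' flagged as skipped, not fatal.
#'
#' @param table data.frame with columns \code{Kd_uM}, \code{dH},
#'   \code{minus_TdS}, \code{dG} (see [read_thermo_table()]).
#' @param temperature Kelvin (default 298.15).
#' @param tol_enthalpy Base tolerance for dH + (-TdS) = dG (default 0,
#'   i.e. exact at printed precision).
#' @param tol_rtln Base tolerance for R T ln Kd = dG (default 0.1 kcal/mol).
#' @param printed_ulp Last printed digit (default 0.1 kcal/mol).
#' @return \code{thermo_closure} data.frame: per-row computed closure,
#'   R T ln Kd, both pass flags, plus an \code{overall_pass} attribute
#'   (TRUE iff every checkable row passes both).
#' @export
thermo_closure_report <- function(table, temperature = 298.15,
                                  tol_enthalpy = 0, tol_rtln = 0.1,
                                  printed_ulp = 0.1) {
  need <- c("Kd_uM", "dH", "minus_TdS", "dG")
  stopifnot(all(need %in% names(table)))
  half_ulp <- printed_ulp / 2
  num <- function(x) suppressWarnings(as.numeric(x))
  Kd <- num(table$Kd_uM); dH <- num(table$dH)
  mTdS <- num(table$minus_TdS); dG <- num(table$dG)
  checkable <- !(is.na(Kd) | is.na(dH) | is.na(mTdS) | is.na(dG))
  closure <- dH + mTdS
  rtln <- ifelse(is.na(Kd) | Kd <= 0, NA_real_,
                 delta_g_from_kd(Kd * 1e-6, temperature))
  ok_enthalpy <- checkable & abs(closure - dG) <= tol_enthalpy + half_ulp
  ok_rtln <- checkable & abs(rtln - dG) <= tol_rtln + half_ulp
  out <- cbind(table,
               data.frame(closure_dG = closure, rtln_dG = rtln,
                          checkable = checkable,
                          pass_enthalpy = ok_enthalpy,
                          pass_rtln = ok_rtln,
                          pass = ok_enthalpy & ok_rtln))
  attr(out, "overall_pass") <- all(out$pass[out$checkable])
  class(out) <- c("thermo_closure", "data.frame")
  out
}

#' @export
print.thermo_closure <- function(x, ...) {
  cat("Thermodynamic closure report (T =", "25 C assumed unless set)\n")
  df <- as.data.frame(x)
  df$closure_dG <- round(df$closure_dG, 2)
  df$rtln_dG <- round(df$rtln_dG, 2)
  print(df, row.names = FALSE)
  cat("overall:", if (all(df$pass[df$checkable])) "PASS" else "FAIL", "\n")
  invisible(x)
}

pipeline_log <- function(level, verbose, ...) {
  if (verbose) message("[", level, "] ", ...)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order on seeded synthetic inputs:
#' cohort (genome generation -> anchor detection -> co-transcription ->
#' classification -> summary), conservation (alignment generation ->
#' frequency and differential profiles -> charge summary), itc (titration
#' generation -> binding fit), kinetics (rate-data generation ->
#' Michaelis-Menten fit), and the thermodynamic closure report on the
#' packaged reference table. Writes TSV/JSON artifacts carrying provenance
#' (config hash, seed, package version); reruns of the same config are
#' byte-identical.
#'
#' @param config List (or path to a YAML file) with elements \code{seed},
#'   \code{out_dir}, optional \code{stages} (subset of \code{"cohort"},
#'   \code{"conservation"}, \code{"itc"}, \code{"kinetics"},
#'   \code{"closure"}), optional stage parameter lists (\code{cohort},
#'   \code{conservation}, \code{itc}, \code{kinetics}), and optional
#'   \code{inputs} (named existing file paths, validated up front).
#' @param verbose Log stage progress (default TRUE).
#' @return Invisibly, a list of per-stage results and written file paths;
#'   errors if any stage fails (remaining stages are skipped).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("cohort", "conservation", "itc", "kinetics", "closure")
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  provenance <- list(config_hash = hash, seed = seed,
                     package_version =
                       as.character(utils::packageVersion("heliomod")))
  write_json <- function(x, file) {
    jsonlite::write_json(c(list(provenance = provenance), x),
                         file.path(config$out_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    file
  }
  write_tsv <- function(x, file) {
    utils::write.table(x, file.path(config$out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  results <- list()
  files <- character(0)
  failed <- NULL
  for (stage in stages) {
    if (!is.null(failed)) {
      pipeline_log("WARN", verbose, "skipping stage '", stage,
                   "' after failure in '", failed, "'")
      next
    }
    pipeline_log("INFO", verbose, "stage: ", stage)
    res <- tryCatch(switch(stage,
      cohort = {
        p <- config$cohort
        gen <- generate_genome_cohort(
          n_genomes = p$n_genomes %||% 100L,
          co_rate = p$co_rate %||% 0.386,
          seed = seed)
        anchors <- find_anchor_genes(gen$genes, hits = gen$hits)
        units <- lapply(anchors$gene_id, function(id)
          neighborhood(gen$genes, id))
        classified <- classify_cohort(units)
        summ <- summarize_cohort(classified)
        files <- c(files,
                   write_tsv(classified, "cohort_classification.tsv"),
                   write_json(unclass(summ), "cohort_summary.json"))
        list(classified = classified, summary = summ, truth = gen$truth)
      },
      conservation = {
        p <- config$conservation
        enr <- p$enrichment %||% data.frame(
          group = "abc_transporter", position = 229L, aa = "R",
          delta = 0.3)
        aln <- generate_labeled_alignment(
          n_per_group = unlist(p$n_per_group %||%
                                 c(abc_transporter = 120,
                                   non_co_transcription = 120)),
          enrichment = enr, seed = seed)
        grp <- setdiff(unique(aln$group), "non_co_transcription")[1]
        prof_g <- frequency_per_her(aln, group_label = grp)
        prof_b <- frequency_per_her(aln,
                                    group_label = "non_co_transcription")
        diffp <- differential_frequency(prof_g, prof_b,
                                        theta = p$theta %||% 0.19)
        charge <- charge_conservation_by_region(prof_g)
        long <- data.frame(
          position = rep(as.integer(colnames(diffp$delta)),
                         each = nrow(diffp$delta)),
          aa = rep(rownames(diffp$delta), ncol(diffp$delta)),
          delta = as.vector(diffp$delta))
        files <- c(files,
                   write_tsv(long, "conservation_differential.tsv"),
                   write_tsv(diffp$flags_up, "conservation_flags_up.tsv"),
                   write_json(list(per_position = charge$per_position),
                              "charge_summary.json"))
        list(differential = diffp, charge = charge)
      },
      itc = {
        p <- config$itc
        expt <- generate_itc(
          params = p$params %||% list(n = 1, Ka = 1 / 91.6e-6, dH = 48.9,
                                      q_offset = 0),
          model = p$model %||% "one_site",
          noise_sd = p$noise_sd %||% 0.02, seed = seed)
        fit <- fit_binding(expt, model = p$model %||% "one_site")
        files <- c(files,
                   write_json(list(model = fit$model, params = fit$params,
                                   thermo = fit$thermo, rss = fit$rss,
                                   diagnostics = fit$diagnostics),
                              "itc_fit.json"),
                   write_tsv(data.frame(injection =
                                          seq_along(fit$observed),
                                        observed = fit$observed,
                                        fitted = fit$fitted),
                             "itc_curve.tsv"))
        fit
      },
      kinetics = {
        p <- config$kinetics
        dat <- generate_kinetics("mm",
                                 params = p$params %||%
                                   list(Vmax = 17.6, Km = 19.2),
                                 noise_sd = p$noise_sd %||% 0.02,
                                 seed = seed)
        fit <- fit_mm(dat$S, dat$v, E_total = p$E_total %||% 1)
        files <- c(files,
                   write_json(list(params = fit$params, rss = fit$rss),
                              "kinetics_mm.json"),
                   write_tsv(cbind(dat, fitted = fit$fitted),
                             "kinetics_mm_curve.tsv"))
        fit
      },
      closure = {
        rep <- thermo_closure_report(read_thermo_table())
        files <- c(files, write_tsv(as.data.frame(rep),
                                    "thermo_closure.tsv"))
        rep
      },
      stop("unknown stage: ", stage)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      pipeline_log("ERROR", verbose, "stage '", stage, "' failed: ",
                   conditionMessage(res))
      failed <- stage
      results[[stage]] <- res
    } else {
      results[[stage]] <- res
    }
  }
  if (!is.null(failed))
    stop("pipeline stage '", failed, "' failed: ",
         conditionMessage(results[[failed]]))
  write_json(list(stages = stages, files = files), "provenance.json")
  invisible(list(results = results, files = files, provenance = provenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
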