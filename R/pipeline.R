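#' Validate a dataset directory
#'
#' Checks shapes, vocabularies, parcel-count consistency and FD presence of a
#' dataset written by [generate_dataset()] (or laid out the same way). Always
#' returns a report rather than erroring.
#'
#' @param dir Dataset directory.
#' @return Object of class `validation_report`: `pass` (logical) and
#'   `issues` (character vector with row-level diagnostics).
#' @export
validate_inputs <- function(dir) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, sprintf(...))
  need <- c("subjects.tsv", "blocks.tsv", "region_labels.tsv",
            "manifest.json")
  for (f in need)
    if (!file.exists(file.path(dir, f))) note("missing file: %s", f)
  if (length(issues))
    return(structure(list(pass = FALSE, issues = issues),
                     class = "validation_report"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  p <- man$p
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"))
  blocks <- utils::read.delim(file.path(dir, "blocks.tsv"))
  labs <- utils::read.delim(file.path(dir, "region_labels.tsv"))

  if (!all(c("fd_mean", "fd_max") %in% names(blocks)))
    note("block table lacks FD columns")
  bad_cond <- which(!blocks$condition %in% c("zero_back", "two_back"))
  for (r in utils::head(bad_cond, 5))
    note("blocks.tsv row %d: unknown condition '%s'", r, blocks$condition[r])
  bad_win <- which(blocks$onset_tr < 0 | blocks$onset_tr >= blocks$offset_tr)
  for (r in utils::head(bad_win, 5))
    note("blocks.tsv row %d: invalid block window [%s, %s)", r,
         blocks$onset_tr[r], blocks$offset_tr[r])
  if (nrow(labs) != p)
    note("region labels cover %d parcels, manifest says %d", nrow(labs), p)
  if (any(labs$parcel_id < 0 | labs$parcel_id >= p))
    note("region labels reference a parcel outside [0, %d)", p)
  mask_dir <- file.path(dir, "masks")
  if (dir.exists(mask_dir)) {
    for (f in list.files(mask_dir, full.names = TRUE)) {
      m <- utils::read.delim(f)
      bad <- which(m$i < 0 | m$j >= p | m$i >= m$j)
      for (r in utils::head(bad, 5))
        note("%s row %d: edge (%d, %d) invalid for %d parcels (0-based)",
             basename(f), r, m$i[r], m$j[r], p)
    }
  }
  if (!all(blocks$subject_id %in% subjects$subject_id))
    note("block table references unknown subjects")
  structure(list(pass = length(issues) == 0, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$pass) "validation: PASS\n"
      else paste0("validation: FAIL\n  ",
                  paste(x$issues, collapse = "\n  "), "\n"))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param sim Arguments forwarded to [sim_config()].
#' @param stages Named logical toggles: `strength`, `cpm`, `overlap`,
#'   `lesion`, `pls`.
#' @param fd_profile `"strict"` or `"liberal"`.
#' @param alpha CPM selection threshold.
#' @param n_perm,n_boot PLS / lesion inference sizes.
#' @param lesion_regions Regions to lesion (`NULL` = all).
#' @return Nested list understood by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, sim = list(p = 40, n_per_group = 60),
                            stages = list(strength = TRUE, cpm = TRUE,
                                          overlap = TRUE, lesion = TRUE,
                                          pls = TRUE),
                            fd_profile = "strict", alpha = 0.01,
                            n_perm = 100, n_boot = 100,
                            lesion_regions = NULL) {
  list(out_dir = out_dir, sim = sim, stages = stages,
       fd_profile = fd_profile, alpha = alpha,
       n_perm = n_perm, n_boot = n_boot, lesion_regions = lesion_regions)
}

check_pipeline_config <- function(config) {
  known <- c("out_dir", "sim", "stages", "fd_profile", "alpha",
             "n_perm", "n_boot", "lesion_regions", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(config$out_dir)) stop("config needs out_dir")
  stages_known <- c("strength", "cpm", "overlap", "lesion", "pls")
  extra_s <- setdiff(names(config$stages), stages_known)
  if (length(extra_s))
    stop("unknown stage toggles: ", paste(extra_s, collapse = ", "))
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [pipeline_config()]'s structure.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  check_pipeline_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates simulate -> strength -> cpm -> overlap -> lesion -> pls with
#' one seed, writing TSV/JSON outputs plus a manifest with per-file checksums
#' and per-stage status. Stage failures stop the run with a stage-tagged
#' error.
#'
#' @param config Pipeline configuration ([pipeline_config()] or a validated
#'   YAML file).
#' @param seed Global seed (overridden by `config$seed` when present).
#' @return The manifest list, invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, seed = 1) {
  check_pipeline_config(config)
  if (!is.null(config$seed)) seed <- config$seed
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  status <- list()
  wt <- function(df, f) {
    utils::write.table(df, file.path(out, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(out, f), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    files <<- c(files, f)
  }
  stage <- function(name, enabled, fn) {
    if (!enabled) {
      status[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    status[[name]] <<- "ok"
    res
  }

  study <- stage("simulate", TRUE, function()
    simulate_study(do.call(sim_config, config$sim), seed = seed))
  wt(study$subjects, "subjects.tsv")

  bs <- study$connectomes$block_strengths
  retained <- NULL
  scores <- stage("strength", isTRUE(config$stages$strength), function() {
    mf <- motion_filter(bs, profile = config$fd_profile)
    retained <<- mf$retained
    writeLines(mf$log, file.path(out, "exclusions.log"))
    files <<- c(files, "exclusions.log")
    sc <- condition_strengths(
      data.frame(subject_id = mf$retained$subject_id,
                 condition = mf$retained$condition,
                 strength = mf$retained$strength_sa),
      "zero_back")
    wt(sc, "sa_strength_0back.tsv")
    sc
  })

  acc0 <- mean_accuracy(study, "zero_back")
  fit_cpm <- stage("cpm", isTRUE(config$stages$cpm), function() {
    fit <- cpm(study$connectomes$edges_mean,
               acc0$accuracy[match(study$subjects$subject_id,
                                   acc0$subject_id)],
               study$subjects$site, alpha = config$alpha,
               p = study$config$p)
    wt(mask_edges(fit$consensus), "consensus_mask.tsv")
    rep <- summary(fit)$prediction
    wj(list(r = rep$r, rho = rep$rho, n = rep$n,
            alpha = fit$alpha,
            consensus_edges = fit$consensus$n_pos + fit$consensus$n_neg),
       "cpm_report.json")
    fit
  })

  stage("overlap", isTRUE(config$stages$overlap), function() {
    gm <- study$ground_truth$masks
    ov <- list(
      pos = network_overlap(gm$sa_pos, gm$wm_pos, c("pos", "pos")),
      neg = network_overlap(gm$sa_neg, gm$wm_neg, c("neg", "neg")))
    wj(lapply(ov, function(o)
      list(x = o$x, K = o$K, N = o$N, M = o$M,
           pct_combined = o$pct_combined, p_gt = o$p_gt, p_ge = o$p_ge)),
      "overlap.json")
    ov
  })

  stage("lesion", isTRUE(config$stages$lesion), function() {
    sa <- combine_masks(study$ground_truth$masks$sa_pos,
                        study$ground_truth$masks$sa_neg, "sa")
    prof <- lesion_profile(study$connectomes$edges_cond$zero_back,
                           acc0$accuracy, sa, study$region_labels)
    if (!is.null(config$lesion_regions))
      prof <- prof[prof$region %in% config$lesion_regions, , drop = FALSE]
    wt(prof, "lesion_profile.tsv")
    prof
  })

  stage("pls", isTRUE(config$stages$pls), function() {
    fit <- bpls(study$connectomes$edges_mean, acc0$accuracy,
                study$subjects$group, n_perm = config$n_perm,
                n_boot = config$n_boot, seed = derive_seed(seed, 31),
                p = study$config$p)
    wj(list(sigma_frac = fit$sigma_frac, perm_p = fit$perm_p,
            n_sig_edges = vapply(fit$sig_edges, length, integer(1))),
       "pls_report.json")
    wt(data.frame(edge = seq_len(nrow(fit$U)),
                  salience_lv1 = fit$U[, 1], salience_lv2 = fit$U[, 2],
                  zbr_lv1 = fit$boot_ratio[, 1],
                  zbr_lv2 = fit$boot_ratio[, 2]),
       "pls_saliences.tsv")
    fit
  })

  # wall clock lives in an unchecksummed side file so the manifest itself is
  # byte-identical across reruns with the same config and seed
  writeLines(sprintf("wall_clock_s\t%.3f",
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             file.path(out, "timing.log"))
  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    stages = status,
    n_blocks_excluded = if (is.null(retained)) NA
                        else nrow(bs) - nrow(retained),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)),
    unchecksummed_files = list("timing.log"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
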