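#' End-to-end study configuration
#'
#' Bundles everything [run_study()] needs: where the data come from (a
#' [study_spec()] to generate, or a fixture directory), the electrode-group
#' map, the PSO settings used per segment, the PDC band and order range,
#' the reference condition of the post-hoc tests, and the global seed that
#' determines every random draw.
#'
#' @param fixture_spec a [study_spec()] used to generate the emulated study
#'   (ignored when `fixture_dir` is given).
#' @param fixture_dir optional directory written by
#'   [generate_study_fixture()].
#' @param groups electrode-group map (list `VC`, `FA`).
#' @param pso a [pso_config()] for the per-segment inversions.
#' @param band PDC averaging band, Hz.
#' @param order_range AIC search range `c(p_min, p_max)` for the MVAR fits.
#' @param reference reference condition of the post-hoc tests.
#' @param seed global seed.
#' @param do_inversion,do_pdc enable/disable the two analysis branches.
#' @param cache_dir optional directory for per-segment inversion caching
#'   (the pipeline is restartable: cached segment results are reused).
#' @return A list of class `study_config`.
#' @export
study_config <- function(fixture_spec = study_spec(), fixture_dir = NULL,
                         groups = default_electrode_groups(),
                         pso = pso_config(), band = c(6, 92),
                         order_range = c(5, 20), reference = "8",
                         seed = 1L, do_inversion = TRUE, do_pdc = TRUE,
                         cache_dir = NULL) {
  structure(list(fixture_spec = fixture_spec, fixture_dir = fixture_dir,
                 groups = groups, pso = pso, band = band,
                 order_range = order_range, reference = reference,
                 seed = as.integer(seed), do_inversion = do_inversion,
                 do_pdc = do_pdc, cache_dir = cache_dir),
            class = "study_config")
}

#' Hash of a configuration object
#'
#' Canonical-JSON md5, embedded in every results bundle so outputs can be
#' traced to the exact configuration that produced them.
#'
#' @param config any serializable object.
#' @return Character md5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full two-branch study analysis
#'
#' Model-driven branch: every segment's two-channel recording is inverted by
#' PSO (shared-noise protocol), couplings are averaged across the segments
#' of each subject x condition cell, and each coupling's subjects x
#' conditions table is tested with the Greenhouse-Geisser-corrected
#' repeated-measures ANOVA plus Bonferroni paired t post-hocs against the
#' reference condition. Data-driven branch: every montage segment goes
#' through AIC order selection, MVAR fit, PDC, band averaging and VC/FA
#' aggregation; the four flow measures are averaged across segments and
#' tested the same way.
#'
#' @param config a [study_config()].
#' @param fixture optionally a pre-generated `study_fixture` (overrides
#'   `config$fixture_spec` / `config$fixture_dir`).
#' @param progress emit per-stage messages.
#' @return A list of class `study_results`: `config_hash`, `seed`,
#'   `parameters` (long data.frame of per-subject couplings), `flows`,
#'   `anova` (per measure), `posthoc` (per measure), `condition_means`.
#' @export
run_study <- function(config = study_config(), fixture = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  if (is.null(fixture)) {
    if (!is.null(config$fixture_dir)) {
      fixture <- load_study_fixture(config$fixture_dir)
    } else {
      say("generating study fixture (seed %d)", config$fixture_spec$seed)
      fixture <- generate_study_fixture(config$fixture_spec)
    }
  }
  spec <- fixture$spec
  conds <- spec$conditions
  nsub <- spec$subjects
  check_design_complete(fixture)

  swarm_seeds <- with_seed(config$seed + 1L,
    matrix(sample.int(.Machine$integer.max,
                      nsub * length(conds) * spec$segments),
           nrow = nsub * length(conds)))

  params_rows <- list(); flow_rows <- list()
  idx <- 0L
  for (s in seq_len(nsub)) {
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      idx <- idx + 1L
      cell <- fixture$segments[[s]][[cond]]
      if (config$do_inversion) {
        res <- lapply(seq_len(spec$segments), function(g) {
          cached_invert(cell[[g]]$model, config, swarm_seeds[idx, g],
                        s, cond, g)
        })
        avg <- average_segment_results(res)
        params_rows[[length(params_rows) + 1L]] <- data.frame(
          subject = s, condition = cond,
          C1 = avg$C1, C2 = avg$C2, K1 = avg$K1, K2 = avg$K2,
          mean_re = mean(vapply(res, function(r) mean(r$relative_error),
                                numeric(1))))
        say("subject %d %s: inversion done (K1 = %.0f)", s, cond, avg$K1)
      }
      if (config$do_pdc) {
        fl <- lapply(seq_len(spec$segments), function(g) {
          seg <- select_channels(cell[[g]]$var,
                                 c(config$groups$VC, config$groups$FA))
          segment_flows(seg, band = config$band, groups = config$groups,
                        p_min = config$order_range[1],
                        p_max = config$order_range[2])$flows
        })
        flow_rows[[length(flow_rows) + 1L]] <- data.frame(
          subject = s, condition = cond,
          vc_to_fa = mean(vapply(fl, `[[`, numeric(1), "vc_to_fa")),
          fa_to_vc = mean(vapply(fl, `[[`, numeric(1), "fa_to_vc")),
          within_vc = mean(vapply(fl, `[[`, numeric(1), "within_vc")),
          within_fa = mean(vapply(fl, `[[`, numeric(1), "within_fa")))
      }
    }
  }
  parameters <- if (length(params_rows)) do.call(rbind, params_rows) else NULL
  flows <- if (length(flow_rows)) do.call(rbind, flow_rows) else NULL

  measures <- c(if (!is.null(parameters)) c("C1", "C2", "K1", "K2"),
                if (!is.null(flows)) c("vc_to_fa", "fa_to_vc",
                                       "within_vc", "within_fa"))
  anova <- list(); posthoc <- list(); cond_means <- list()
  for (msr in measures) {
    src <- if (msr %in% c("C1", "C2", "K1", "K2")) parameters else flows
    tab <- long_to_table(src, msr, conds)
    anova[[msr]] <- rm_anova_gg(tab)
    posthoc[[msr]] <- posthoc_paired_bonferroni(tab, config$reference)
    cond_means[[msr]] <- colMeans(tab$values)
  }
  structure(list(config_hash = config_hash(config), seed = config$seed,
                 parameters = parameters, flows = flows, anova = anova,
                 posthoc = posthoc, condition_means = cond_means),
            class = "study_results")
}

# reshape a long per-subject data.frame into a condition_table for `measure`
long_to_table <- function(df, measure, conds) {
  wide <- sapply(conds, function(cond)
    df[[measure]][df$condition == cond][order(df$subject[df$condition == cond])])
  condition_table(wide, conditions = conds)
}

# design-completeness check: every subject must have every condition cell
check_design_complete <- function(fixture) {
  spec <- fixture$spec
  for (s in seq_len(spec$subjects)) {
    have <- names(fixture$segments[[s]])
    miss <- setdiff(spec$conditions, have)
    if (length(miss))
      stop("incomplete design: subject ", s, " lacks condition(s) ",
           paste(miss, collapse = ", "))
    for (cond in spec$conditions)
      if (length(fixture$segments[[s]][[cond]]) != spec$segments)
        stop("incomplete design: subject ", s, " condition ", cond,
             " has ", length(fixture$segments[[s]][[cond]]),
             " segment(s), expected ", spec$segments)
  }
  invisible(TRUE)
}

# per-segment inversion with optional on-disk caching (restartable pipeline)
cached_invert <- function(model_fixture, config, seed, subject, cond, seg) {
  cache <- config$cache_dir
  if (!is.null(cache)) {
    dir.create(cache, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache, sprintf("inv_s%02d_%s_g%d_%d.json",
                                  subject, cond, seg, seed))
    if (file.exists(f)) {
      j <- jsonlite::read_json(f, simplifyVector = TRUE)
      params <- double_column_params(j$params[1], j$params[2],
                                     j$params[3], j$params[4])
      return(structure(list(params = params, fitness = j$fitness,
                            relative_error = stats::setNames(
                              j$relative_error, c("u1", "u2")),
                            trace = j$trace, generations = j$generations,
                            seeds = c(swarm = seed)),
                       class = "inversion_result"))
    }
  }
  res <- invert_segment(fixture = model_fixture, config = config$pso,
                        seed = seed)
  if (!is.null(cache)) {
    jsonlite::write_json(
      list(params = c(res$params$C1, res$params$C2, res$params$K1,
                      res$params$K2),
           fitness = res$fitness,
           relative_error = unname(res$relative_error),
           trace = res$trace, generations = res$generations),
      f, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Load a written study fixture back into memory
#'
#' Reconstructs the in-memory fixture from a directory written by
#' [generate_study_fixture()]; segments are re-read from the text files and
#' inversion inputs re-derived from the manifest seeds (the manifest
#' records everything needed to recompute each segment bit-identically).
#'
#' @param dir fixture directory.
#' @return A `study_fixture`.
#' @export
load_study_fixture <- function(dir) {
  m <- read_study_manifest(dir)
  spec <- m$spec
  manifest <- m$manifest
  segments <- vector("list", spec$subjects)
  for (s in seq_len(spec$subjects)) {
    segments[[s]] <- stats::setNames(vector("list", length(spec$conditions)),
                                     spec$conditions)
    for (cond in spec$conditions) {
      rows <- manifest[manifest$subject == s & manifest$condition == cond, ]
      seglist <- vector("list", nrow(rows))
      for (g in seq_len(nrow(rows))) {
        row <- rows[rows$segment == g, ]
        params <- double_column_params(row$C1, row$C2, row$K1, row$K2)
        sspec <- stimulus_spec(cond, duration = spec$duration, fs = spec$fs)
        fix <- generate_inversion_fixture(params, sspec, row$seed_model)
        stem <- sprintf("s%02d_%s_seg%d", s, cond, g)
        varseg <- read_segment(file.path(dir, paste0(stem, "_var.tsv")))
        seglist[[g]] <- list(model = fix, var = varseg)
      }
      segments[[s]][[cond]] <- seglist
    }
  }
  structure(list(spec = spec, manifest = manifest, segments = segments),
            class = "study_fixture")
}

#' Write a results bundle to a directory
#'
#' Emits `parameters.tsv`, `flows.tsv`, and `results.json` (ANOVA, post-hoc
#' tables, condition means, config hash and seed).
#'
#' @param results a `study_results` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$parameters))
    utils::write.table(results$parameters, file.path(dir, "parameters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$flows))
    utils::write.table(results$flows, file.path(dir, "flows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = results$config_hash, seed = results$seed,
         anova = lapply(results$anova, unclass),
         posthoc = results$posthoc,
         condition_means = results$condition_means),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", force = TRUE)
  invisible(dir)
}
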