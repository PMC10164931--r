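#' Run a config-driven processing pipeline
#'
#' Executes an ordered list of stages over input files, writing outputs and a
#' JSON provenance record (package version, configuration, per-stage
#' reports). Supported stages: `simulate` (phantom generation +
#' corruption), `denoise` (`method`: vst2d/vst3d/median3d), `drift_correct`
#' (`axis`: t/z), `register3d` (`landmarks`, `reference`), `benchmark`
#' (replicate alignment, averaging ground truth, denoiser comparison). Any
#' unknown stage name or unknown key inside a stage block is a configuration
#' error. Per-file failures in batch mode are logged and skipped; the run
#' fails only on hard errors.
#'
#' @param config path to a YAML file, or an equivalent named list, with
#'   top-level keys `stages` (list of `list(name = ..., params)`), `output_dir`
#'   and optional `seed` (default 1).
#' @return invisibly, the provenance record (named list) also written to
#'   `provenance.json` in `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known_top <- c("stages", "output_dir", "seed", "log_level")
  extra <- setdiff(names(config), known_top)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$stages) || !length(config$stages)) {
    stop("configuration must list at least one stage", call. = FALSE)
  }
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  prov <- list(package = "ivmproc",
               version = as.character(utils::packageVersion("ivmproc")),
               seed = seed, stages = list())
  state <- list(stack = NULL, replicates = NULL, clean = NULL)

  known_stages <- c("simulate", "denoise", "drift_correct", "register3d",
                    "benchmark")
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    nm <- st$name
    if (is.null(nm) || !nm %in% known_stages) {
      stop("unknown stage name: ", nm %||% "<missing>", call. = FALSE)
    }
    rep <- switch(nm,
      simulate = {
        ok_keys(st, c("name", "extents", "n_replicates", "alpha", "sigma",
                      "jitter_um", "out", "n_filaments", "n_tubes",
                      "n_puncta", "n_fibrils"))
        ext <- unlist(st$extents %||% c(3, 12, 3, 64, 64))
        spec <- phantom_spec(extents = ext, seed = seed,
                             n_filaments = st$n_filaments %||% 6L,
                             n_tubes = st$n_tubes %||% 2L,
                             n_puncta = st$n_puncta %||% 5L,
                             n_fibrils = st$n_fibrils %||% 10L)
        model <- pg_model(alpha = st$alpha %||% 1, sigma = st$sigma %||% 5)
        if (!is.null(st$n_replicates)) {
          v <- make_validation_replicates(spec, n = st$n_replicates,
                                          model = model,
                                          jitter = st$jitter_um %||% 0,
                                          seed = seed)
          state$replicates <- v$replicates
          state$clean <- v$clean
          state$stack <- v$replicates[[1]]
        } else {
          clean <- make_phantom(spec)
          state$clean <- clean
          state$stack <- suppressMessages(
            quantize_to_uint(corrupt(clean, model, seed = seed), 16L))
        }
        if (!is.null(st$out)) {
          write_stack(state$stack, file.path(out_dir, st$out))
        }
        list(stage = nm, extents = as.integer(ext))
      },
      denoise = {
        ok_keys(st, c("name", "method", "chunk", "overlap", "tile_slices",
                      "inverse", "in", "out"))
        input <- if (!is.null(st[["in"]])) read_stack(st[["in"]]) else state$stack
        if (is.null(input)) stop("denoise stage has no input", call. = FALSE)
        cfg <- vst_config(chunk_length = st$chunk %||% 10L,
                          chunk_overlap = st$overlap %||% 5L,
                          tile_max_slices = st$tile_slices %||% 10L,
                          inverse_mode = st$inverse %||% "exact_unbiased")
        den <- denoise_vst(input, cfg, method = st$method %||% "vst3d")
        state$stack <- den
        if (!is.null(st$out)) write_stack(den, file.path(out_dir, st$out))
        list(stage = nm, method = st$method %||% "vst3d",
             sigma = attr(den, "sigma_report")$sigma)
      },
      drift_correct = {
        ok_keys(st, c("name", "axis", "mode", "in", "out", "shifts_out"))
        input <- if (!is.null(st[["in"]])) read_stack(st[["in"]]) else state$stack
        if (is.null(input)) stop("drift_correct stage has no input", call. = FALSE)
        res <- register_2d(input, axis = st$axis %||% "t",
                           mode = st$mode %||% "sequential")
        state$stack <- res$stack
        if (!is.null(st$out)) write_stack(res$stack, file.path(out_dir, st$out))
        if (!is.null(st$shifts_out)) {
          utils::write.csv(res$shifts, file.path(out_dir, st$shifts_out),
                           row.names = FALSE)
        }
        list(stage = nm, n_flagged = sum(res$shifts$flagged))
      },
      register3d = {
        ok_keys(st, c("name", "landmarks", "reference", "in", "out",
                      "report_out"))
        input <- if (!is.null(st[["in"]])) read_stack(st[["in"]]) else state$stack
        refst <- read_stack(st$reference)
        lm <- read_landmarks(st$landmarks)
        res <- register_serial(input, refst, lm)
        state$stack <- res$aligned
        if (!is.null(st$out)) write_stack(res$aligned, file.path(out_dir, st$out))
        list(stage = nm, rms_um = attr(res$report, "rms"))
      },
      benchmark = {
        ok_keys(st, c("name", "methods", "out"))
        if (is.null(state$replicates)) {
          stop("benchmark stage requires a preceding simulate stage with ",
               "n_replicates", call. = FALSE)
        }
        al <- align_replicates_translation(state$replicates)
        gt <- generate_ground_truth(al$aligned)
        mnames <- st$methods %||% c("median3d")
        fns <- lapply(mnames, function(m) {
          force(m); function(s) denoise_vst(s, method = m)
        })
        names(fns) <- mnames
        repn <- benchmark_denoisers(state$replicates, gt, fns)
        if (!is.null(st$out)) {
          utils::write.csv(repn$rows, file.path(out_dir, st$out),
                           row.names = FALSE)
        }
        list(stage = nm,
             summary = as.data.frame(repn$summary))
      })
    prov$stages[[si]] <- rep
  }
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(prov)
}

ok_keys <- function(st, allowed) {
  extra <- setdiff(names(st), allowed)
  if (length(extra)) {
    stop("unknown key(s) in stage '", st$name, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
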