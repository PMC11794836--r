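#' Fit the full hybrid model on a dataset split
#'
#' The package's front door: pretrains the autoencoder on the unlabeled
#' normal split, trains the classifier head on the frozen encoder, then
#' fine-tunes the last two encoder layers jointly with the head under
#' class-weighted cross-entropy.
#'
#' @param split A `karyo_split` from [make_split()] (or any list with
#'   `unlabeled_train`, `labeled_train`, `validation` elements).
#' @param ae_cfg An [ae_config()].
#' @param clf_cfg A [clf_config()] for the frozen stage.
#' @param ft_cfg A [clf_config()] for the fine-tuning stage (defaults to
#'   `clf_cfg` with a shifted seed).
#' @param seed Seed for autoencoder weight initialization.
#' @return A fine-tuned `karyo_hybrid` model; the pretrained autoencoder
#'   is attached as attribute `"autoencoder"`.
#' @export
karyo_fit <- function(split, ae_cfg = ae_config(), clf_cfg = clf_config(),
                      ft_cfg = NULL, seed = 1L) {
  ft_cfg <- ft_cfg %||% {
    cfg <- clf_cfg
    cfg$seed <- derive_seed(clf_cfg$seed, 1L)
    cfg
  }
  ae <- build_autoencoder(seed = seed)
  ae <- train_autoencoder(ae, split$unlabeled_train, split$validation, ae_cfg)
  model <- train_frozen(ae, split$labeled_train, clf_cfg)
  model <- fine_tune(model, split$labeled_train, ft_cfg)
  attr(model, "autoencoder") <- ae
  model
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Base seed; stage seeds are derived from it.
#' @param split A [split_config()].
#' @param ae An [ae_config()].
#' @param clf,ft [clf_config()]s for the frozen and fine-tune stages.
#' @param localizer A [localizer_config()].
#' @param stages Which stages to execute; disabled stages load their
#'   inputs from checkpoints in `out_dir`.
#' @param write_images If `TRUE`, [write_split()] writes the full image
#'   set (slow for large splits).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, split = split_config(),
                       ae = ae_config(), clf = clf_config(), ft = NULL,
                       localizer = localizer_config(),
                       stages = c("generate", "pretrain", "train", "finetune",
                                  "evaluate", "localize"),
                       write_images = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), split = split,
                 ae = ae, clf = clf, ft = ft, localizer = localizer,
                 stages = stages, write_images = write_images),
            class = "run_config")
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end pipeline
#'
#' Generate (or reload) the synthetic split, pretrain the autoencoder,
#' train and fine-tune the classifier, evaluate on the test split, and
#' localize anomalies on every test image flagged abnormal. Each stage
#' writes a checkpoint plus its logs under `config$out_dir`; disabled
#' stages are reloaded from checkpoints, so `stages = "evaluate"` on a
#' completed run reproduces the stored report.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `model`, the
#'   `evaluation_report`, the localization reports, and artifact paths.
#' @export
karyo_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) s %in% config$stages
  ckpt <- function(name) file.path(out, paste0(name, ".rds"))
  load_ckpt <- function(name) {
    p <- ckpt(name)
    if (!file.exists(p)) {
      stop("no '", name, "' checkpoint in ", out, "; run its stage first",
           call. = FALSE)
    }
    readRDS(p)
  }

  split <- stage_guard("generate", {
    if (on("generate")) {
      sp <- make_split(config$split, seed = derive_seed(config$seed, 101L))
      saveRDS(sp, ckpt("split"))
      counts <- as.data.frame(sp$counts)
      counts$split <- rownames(sp$counts)
      write.csv(counts[c("split", "normal", "abnormal")],
                file.path(out, "split_manifest.csv"), row.names = FALSE)
      if (config$write_images) write_split(sp, file.path(out, "images"))
      sp
    } else load_ckpt("split")
  })

  ae <- stage_guard("pretrain", {
    if (on("pretrain")) {
      cfg <- config$ae
      cfg$seed <- derive_seed(config$seed, 202L)
      m <- build_autoencoder(seed = derive_seed(config$seed, 201L))
      m <- train_autoencoder(m, split$unlabeled_train, split$validation, cfg)
      saveRDS(m, ckpt("autoencoder"))
      write.csv(m$history, file.path(out, "loss_pretrain.csv"), row.names = FALSE)
      m
    } else load_ckpt("autoencoder")
  })

  frozen <- stage_guard("train", {
    if (on("train")) {
      cfg <- config$clf
      cfg$seed <- derive_seed(config$seed, 303L)
      m <- train_frozen(ae, split$labeled_train, cfg)
      saveRDS(m, ckpt("frozen"))
      write.csv(m$history$frozen, file.path(out, "loss_frozen.csv"),
                row.names = FALSE)
      m
    } else load_ckpt("frozen")
  })

  model <- stage_guard("finetune", {
    if (on("finetune")) {
      cfg <- config$ft %||% config$clf
      cfg$seed <- derive_seed(config$seed, 404L)
      m <- fine_tune(frozen, split$labeled_train, cfg)
      saveRDS(m, ckpt("model"))
      write.csv(m$history$fine_tune, file.path(out, "loss_finetune.csv"),
                row.names = FALSE)
      m
    } else load_ckpt("model")
  })

  report <- stage_guard("evaluate", {
    if (on("evaluate")) {
      pred <- predict(model, split$test)
      truth <- image_labels(split$test)
      rep <- evaluation_report(truth, pred$abnormal, pred$score)
      write_report(rep, out)
      rep
    } else {
      jsonlite::read_json(file.path(out, "report.json"))
    }
  })

  locs <- stage_guard("localize", {
    if (!on("localize")) return(NULL)
    pred <- predict(model, split$test)
    flagged <- which(pred$abnormal)
    partners <- config$split$translocation_partners
    ref_cache <- list()
    reference_for <- function(cl) {
      if (is.null(ref_cache[[cl]])) {
        ref_cache[[cl]] <<- standardize(
          render_chromosome(canonical_pattern(cl), noise_sd = 0))
      }
      ref_cache[[cl]]
    }
    reports <- lapply(flagged, function(i) {
      img <- split$test[[i]]
      partner <- if (identical(img$class_id, partners[1])) partners[2] else partners[1]
      localize_translocation(img, reference_for(img$class_id),
                             reference_for(partner), config$localizer)
    })
    obj <- lapply(seq_along(flagged), function(k) {
      r <- reports[[k]]
      list(input = flagged[k], prediction = r$status, regions = r$region,
           donor_class = r$donor_class, match = r$match)
    })
    jsonlite::write_json(obj, file.path(out, "localizations.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
    reports
  })

  prov <- list(seed = config$seed, stages = config$stages,
               r_version = R.version.string,
               package_version = as.character(utils::packageVersion("karyodetect")),
               split_config = unclass(config$split),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(model = model, report = report, localizations = locs,
                 out_dir = out))
}
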