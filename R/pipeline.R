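# End-to-end wiring: simulate -> register -> prm -> stage -> train ->
# evaluate. Every stage reads its inputs from the output directory when an
# earlier stage was run in a previous invocation, so partial reruns resume
# from on-disk artifacts. All artifacts and their digests are recorded in a
# manifest.

PIPELINE_STAGES <- c("simulate", "register", "prm", "stage", "train", "evaluate")

#' Configuration of a full pipeline run
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; stage-specific seeds are derived from it.
#' @param stages character subset of
#'   `c("simulate","register","prm","stage","train","evaluate")`, executed
#'   in canonical order.
#' @param phantom a [phantom_config()] for the simulate stage.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param registration a [registration_settings()] list.
#' @param families model families for train/evaluate.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, stages = PIPELINE_STAGES,
                       phantom = phantom_config(seed = seed),
                       cohort = cohort_config(n = 200L, seed = seed + 1L),
                       registration = registration_settings(),
                       families = c("random_forest", "mlp")) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
                 phantom = phantom, cohort = cohort,
                 registration = registration, families = families),
            class = "run_config")
}

read_phantom_dir <- function(dir) {
  insp <- read_volume_nifti(file.path(dir, "insp.nii.gz"))
  paired_study(insp,
               read_volume_nifti(file.path(dir, "exp.nii.gz")),
               read_volume_nifti(file.path(dir, "lung_mask.nii.gz")) > 0.5,
               round(read_volume_nifti(file.path(dir, "lobe_mask.nii.gz"))),
               voxel_spacing(insp))
}

#' Run the pipeline
#'
#' Executes the configured stages in order. The simulate stage writes a
#' phantom (NIfTI) and a cohort (CSV); register aligns the phantom's
#' expiration onto its inspiration; prm writes the label map and the
#' 72-parameter table (`params.csv`); stage writes the rule-staged cohort;
#' train fits the model set; evaluate writes the full evaluation report
#' (`report.json`). A `manifest.json` with seeds and artifact MD5 digests
#' is written at the end.
#'
#' @param config a [run_config()].
#' @return list with the in-memory artifacts that were produced, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stages <- config$stages
  pdir <- file.path(config$out_dir, "phantom")
  cohort_path <- file.path(config$out_dir, "cohort.csv")

  if ("simulate" %in% stages) {
    out$phantom <- generate_phantom_pair(config$phantom)
    write_phantom(out$phantom, pdir)
    out$cohort <- generate_cohort(config$cohort)
    write_cohort_csv(out$cohort, cohort_path)
  }

  need_study <- function() {
    if (!is.null(out$phantom)) return(out$phantom$study)
    if (!file.exists(file.path(pdir, "insp.nii.gz")))
      stop("register/prm stage needs a phantom; run the simulate stage first")
    read_phantom_dir(pdir)
  }
  need_cohort <- function() {
    if (!is.null(out$cohort)) return(out$cohort)
    if (!file.exists(cohort_path))
      stop("this stage needs a cohort; run the simulate stage first")
    read_cohort_csv(cohort_path)
  }

  if ("register" %in% stages) {
    study <- need_study()
    out$registration <- register_exp_to_insp(study, config$registration)
    study$exp_registered <- out$registration$exp_registered
    out$study <- study
    write_displacement_field(out$registration$field,
                             file.path(config$out_dir, "field.nii.gz"), study$spacing)
    write_volume_nifti(with_spacing(out$registration$exp_registered, study$spacing),
                       file.path(config$out_dir, "exp_registered.nii.gz"))
  }

  if ("prm" %in% stages) {
    study <- if (!is.null(out$study)) out$study else need_study()
    reg_path <- file.path(config$out_dir, "exp_registered.nii.gz")
    if (is.null(study$exp_registered) && file.exists(reg_path))
      study$exp_registered <- read_volume_nifti(reg_path)
    out$prm <- measure_prm(study)
    write_volume_nifti(with_spacing(unclass(out$prm$label_map) + 0, study$spacing),
                       file.path(config$out_dir, "prm_labelmap.nii.gz"))
    utils::write.csv(data.frame(parameter = names(out$prm$parameters),
                                value = as.numeric(out$prm$parameters)),
                     file.path(config$out_dir, "params.csv"), row.names = FALSE)
  }

  if ("stage" %in% stages) {
    staged <- stage_cohort(need_cohort())
    utils::write.csv(staged, file.path(config$out_dir, "staged.csv"), row.names = FALSE)
    out$staged <- staged
  }

  if ("train" %in% stages || "evaluate" %in% stages) {
    out$evaluation <- run_full_evaluation(need_cohort(), seed = config$seed,
                                          families = config$families)
    if ("evaluate" %in% stages)
      write_evaluation_report(out$evaluation, file.path(config$out_dir, "report.json"))
  }

  artifacts <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[!grepl("manifest[.]json$", artifacts)]
  manifest <- list(
    stages = stages, seed = config$seed,
    phantom_seed = config$phantom$seed, cohort_seed = config$cohort$seed,
    artifacts = as.list(stats::setNames(unname(tools::md5sum(artifacts)),
                                        basename(artifacts))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
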