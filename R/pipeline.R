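## One-command orchestration: sample -> select -> stitch -> (cluster) ->
## graft -> score, with validation, manifest and reproducible seeds.

#' Default pipeline run configuration
#'
#' Returns the configuration list the pipeline consumes, either built from
#' the given YAML file or from defaults describing the bundled synthetic
#' system. Keys:
#' \describe{
#'   \item{poi}{`path` to a PDB, or `body: {n_residues, seed, tail}` for a
#'     synthetic body.}
#'   \item{template}{`path` to a receptor YAML, or
#'     `receptor: {groove_width, blocked}` for a synthetic one.}
#'   \item{flexible_span}{integer span override, or `ss` with a per-residue
#'     H/E/C string fed to [determineFlexibleSpan()].}
#'   \item{sampler}{`temperature`, `n_steps`, `n_replicates`,
#'     `save_interval`, `max_torsion_step`, equilibration settings.}
#'   \item{le}{`gridmin`, `gridmax`, `ngrid`, `wles`, `rles`, `cles` (the
#'     distance-grid bias parameters), or `enabled: false`.}
#'   \item{n_select}{random frame selection size (default 10000).}
#'   \item{mode}{`"complete"` or `"clustered"`; `target_k` for the latter.}
#'   \item{seed}{master seed; all stage seeds derive from it.}
#'   \item{out_dir}{artifact directory.}
#' }
#'
#' @param path optional YAML file
#' @return a named list
#' @export
runConfig <- function(path = NULL) {
  cfg <- list(
    poi = list(body = list(n_residues = 20L, seed = 7L, tail = 5L)),
    template = list(receptor = list(groove_width = 1.2, blocked = FALSE)),
    flexible_span = 4L,
    sampler = list(temperature = 600, n_steps = 1000L, n_replicates = 2L,
                   save_interval = 20L, max_torsion_step = 60,
                   equil_stages = 5L, equil_steps_per_stage = 40L,
                   equil_t_start = 60, equil_restraint_k = 2.5e4),
    le = list(gridmin = 0.4, gridmax = 4.0, ngrid = 100L,
              wles = 2.0, rles = 2.5, cles = 2.25e-5, enabled = TRUE),
    n_select = 10000L,
    mode = "complete",
    target_k = 100L,
    seed = 1L,
    out_dir = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; an empty character vector means valid.
#' Checks include: referenced paths exist, the LE grid is well-formed
#' (gridmin < gridmax, ngrid >= 2) and wide enough to cover the peptide's
#' plausible end-to-end range (span+1 residues at ~0.38 nm per residue),
#' mode is known, and the span is a positive integer.
#'
#' @param cfg configuration list from [runConfig()]
#' @return character vector of issues (empty when valid)
#' @export
validateConfig <- function(cfg) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(cfg$poi)) add("poi: missing")
  else if (!is.null(cfg$poi$path) && !file.exists(cfg$poi$path))
    add(paste0("poi.path does not exist: ", cfg$poi$path))
  if (is.null(cfg$template)) add("template: missing")
  else if (!is.null(cfg$template$path) && !file.exists(cfg$template$path))
    add(paste0("template.path does not exist: ", cfg$template$path))
  span <- cfg$flexible_span
  if (!is.null(cfg$ss)) span <- tryCatch(determineFlexibleSpan(cfg$ss),
                                         error = function(e) NULL)
  if (is.null(span) || !is.numeric(span) || span < 1)
    add("flexible_span: must be a positive integer (or a valid ss string)")
  le <- cfg$le
  if (!is.null(le) && !identical(le$enabled, FALSE)) {
    if (!is.null(le$gridmin) && !is.null(le$gridmax) &&
        le$gridmin >= le$gridmax)
      add("le: gridmin must be < gridmax")
    if (!is.null(le$ngrid) && le$ngrid < 2) add("le: ngrid must be >= 2")
    ## the grid must cover the peptide's plausible end-to-end range: flag a
    ## gridmax below typical coil dimensions (~0.25 nm per residue of the
    ## sampled span+1 peptide; full extension is rarely visited)
    if (!is.null(span) && is.numeric(span) &&
        !is.null(le$gridmax) && le$gridmax < 0.25 * (span + 1))
      add("le: gridmax smaller than the peptide's plausible end-to-end reach")
  }
  if (!is.null(cfg$mode) && !cfg$mode %in% c("complete", "clustered"))
    add("mode: must be 'complete' or 'clustered'")
  if (!is.null(cfg$n_select) && cfg$n_select < 1) add("n_select: must be >= 1")
  issues
}

stageLog <- function(stage, t0, inputs = "", outputs = "") {
  message(sprintf("[%s] %.2fs %s -> %s", stage,
                  as.numeric(Sys.time()) - t0, inputs, outputs))
}

## Assemble the POI body and the active-site template from a config.
resolveInputs <- function(cfg) {
  body <- if (!is.null(cfg$poi$path)) readPDB(cfg$poi$path)
  else do.call(makeBody, cfg$poi$body)
  template <- if (!is.null(cfg$template$path)) {
    tpl_cfg <- yaml::read_yaml(cfg$template$path)
    prot <- readPDB(file.path(dirname(cfg$template$path), tpl_cfg$pdb))
    new("ActiveSiteTemplate", protease = prot,
        peptide_resids = setNames(as.integer(unlist(tpl_cfg$residues)),
                                  names(tpl_cfg$residues)),
        peptide_chain = tpl_cfg$chain,
        fit_atoms = unlist(tpl_cfg$fit_atoms))
  } else do.call(makeReceptor, cfg$template$receptor)
  list(body = body, template = template)
}

#' Run the full cleavability pipeline
#'
#' Executes, in order: build or load the inputs; extract the flexible
#' N-terminal peptide sequence (span plus one overlap residue) from the
#' body; sample conformers with the local-elevation-biased torsional
#' search; randomly select up to `n_select` frames; stitch them onto the
#' rigid body, relax and retain negative-energy structures; in clustered
#' mode, reduce the retained set to cluster centers at a cutoff targeting
#' `target_k` clusters; graft each remaining conformer into the active-site
#' template, relax, and retain favorable fits; aggregate into a
#' [CleavabilityReport-class]. All stage seeds derive from `cfg$seed`, and a
#' rerun with an identical configuration reproduces the report exactly.
#' When `cfg$out_dir` is set, stage artifacts (ensemble, stitched frames,
#' energy and outcome tables, report and manifest JSON) are written there.
#'
#' @param cfg configuration list from [runConfig()]
#' @return the [CleavabilityReport-class]; attribute `"artifacts"` lists the
#'   per-stage results (plan, energies, outcomes, clustering if any,
#'   manifest)
#' @export
runPipeline <- function(cfg = runConfig()) {
  issues <- validateConfig(cfg)
  if (length(issues) > 0)
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  manifest <- list(package = as.character(packageVersion("cleavescan")),
                   seed = cfg$seed, mode = cfg$mode, stages = list())
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(NULL)
    p <- file.path(out_dir, name)
    writer(p)
    p
  }

  ## stage 1-2: inputs and flexible span
  t0 <- as.numeric(Sys.time())
  inp <- resolveInputs(cfg)
  body <- inp$body; template <- inp$template
  span <- if (!is.null(cfg$ss)) determineFlexibleSpan(cfg$ss)
  else as.integer(cfg$flexible_span)
  ba <- body@atoms
  core_res <- setdiff(sort(unique(ba$resid[ba$chain == ba$chain[1]])),
                      c(0L, max(ba$resid)))
  if (span + 1L > max(core_res))
    stop("flexible span exceeds the body length")
  seq3 <- vapply(seq_len(span + 1L),
                 function(r) ba$resname[ba$resid == r][1], "")
  manifest$stages$inputs <- list(body = body@label,
                                 template = template@protease@label,
                                 span = span, peptide = paste(seq3, collapse = "-"))
  stageLog("inputs", t0, body@label, sprintf("span=%d", span))

  ## stage 3: conformational sampling
  t0 <- as.numeric(Sys.time())
  pep <- makePeptide(seq3, "extended", capped = TRUE, chain = ba$chain[1])
  sc <- cfg$sampler
  s_cfg <- samplerConfig(
    temperature = sc$temperature, n_steps = sc$n_steps,
    n_replicates = sc$n_replicates, seed = cfg$seed,
    equil_stages = sc$equil_stages,
    equil_steps_per_stage = sc$equil_steps_per_stage,
    equil_t_start = sc$equil_t_start,
    equil_restraint_k = sc$equil_restraint_k,
    save_interval = sc$save_interval,
    max_torsion_step = sc$max_torsion_step)
  le_cfg <- if (identical(cfg$le$enabled, FALSE)) NULL
  else leConfig(cfg$le$gridmin, cfg$le$gridmax, cfg$le$ngrid,
                cfg$le$wles, cfg$le$rles, cfg$le$cles)
  ens <- sampleConformers(pep, s_cfg, le_cfg)
  manifest$stages$sample <- list(n_frames = nFrames(ens),
                                 n_replicates = s_cfg@n_replicates,
                                 n_steps = s_cfg@n_steps, seed = s_cfg@seed)
  emit("ensemble.pdb", function(p) writePDB(ens, p))
  stageLog("sample", t0, pep@label, sprintf("%d frames", nFrames(ens)))

  ## stage 3b: random frame selection
  t0 <- as.numeric(Sys.time())
  sel_seed <- (cfg$seed + 77003L) %% .Machine$integer.max
  sel <- suppressWarnings(randomFrameSelection(ens, cfg$n_select, sel_seed))
  manifest$stages$select <- list(n = nFrames(sel), seed = sel_seed)
  stageLog("select", t0, sprintf("%d frames", nFrames(ens)),
           sprintf("%d frames", nFrames(sel)))

  ## stage 4: stitch, relax, filter
  t0 <- as.numeric(Sys.time())
  plan <- ligationPlan(body, span, chain = ba$chain[1])
  st <- stitchEnsemble(sel, body, plan)
  kept_ids <- st$retained
  if (length(kept_ids) == 0) {
    res <- structure(new("CleavabilityReport", n_total = 0L, n_retained = 0L,
                         fraction_fitted = 0, median_E_bulk = NA_real_,
                         mode = cfg$mode), empty_retention = TRUE)
    warning("no stitched structure passed the energy filter")
    return(res)
  }
  stitched <- Ensemble(st$ensemble@topology, st$ensemble@frames[kept_ids],
                       provenance = st$ensemble@provenance[kept_ids, ,
                                                          drop = FALSE])
  manifest$stages$stitch <- list(n_in = nFrames(sel),
                                 n_retained = length(kept_ids))
  emit("stitched.pdb", function(p) writePDB(stitched, p))
  emit("stitch_energies.tsv", function(p)
    write.table(st$energies, p, sep = "\t", row.names = FALSE, quote = FALSE))
  stageLog("stitch", t0, sprintf("%d frames", nFrames(sel)),
           sprintf("%d retained", length(kept_ids)))

  ## stage 5: clustering (clustered mode)
  work <- stitched
  clustering <- NULL
  if (identical(cfg$mode, "clustered")) {
    t0 <- as.numeric(Sys.time())
    bulk_res <- paste0(span + 2L, ":", max(core_res))
    rm <- rmsdMatrix(stitched,
                     align_sel = paste("backbone3 and resid", bulk_res),
                     rmsd_sel = paste("backbone3 and resid",
                                      paste0("1:", span)))
    ck <- suppressWarnings(cutoffForTargetK(rm, cfg$target_k))
    clustering <- ck$clustering
    work <- centralMembers(clustering, stitched)
    manifest$stages$cluster <- list(cutoff = ck$cutoff,
                                    achieved_k = ck$achieved_k)
    emit("clusters.tsv", function(p) {
      asg <- clusterAssignments(clustering)
      write.table(asg, p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
    stageLog("cluster", t0, sprintf("%d frames", nFrames(stitched)),
             sprintf("%d clusters @ %.4f nm", ck$achieved_k, ck$cutoff))
  }

  ## stage 6-7: graft into the active site, relax, filter
  t0 <- as.numeric(Sys.time())
  outcomes <- fitEnsemble(work, template, nterm_resids = 0:span)
  manifest$stages$graft <- list(n = nrow(outcomes),
                                n_retained = sum(outcomes$retained))
  emit("outcomes.tsv", function(p)
    write.table(outcomes, p, sep = "\t", row.names = FALSE, quote = FALSE))
  stageLog("graft", t0, sprintf("%d conformers", nFrames(work)),
           sprintf("%d retained", sum(outcomes$retained)))

  ## stage 8: score
  report <- cleavabilityScore(outcomes, mode = cfg$mode)
  emit("report.json", function(p) writeReport(report, p, "json"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  attr(report, "artifacts") <- list(plan = plan, energies = st$energies,
                                    outcomes = outcomes,
                                    clustering = clustering,
                                    manifest = manifest)
  report
}

#' Frame-to-cluster assignment table
#' @param clustering a [Clustering-class]
#' @return data.frame: `frame_id`, `cluster_id`, `is_center`
#' @export
clusterAssignments <- function(clustering) {
  rows <- lapply(seq_along(clustering@members), function(ci) {
    m <- clustering@members[[ci]]
    data.frame(frame_id = m, cluster_id = ci,
               is_center = m == clustering@centers[ci])
  })
  out <- do.call(rbind, rows)
  out[order(out$frame_id), , drop = FALSE]
}
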