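# End-to-end orchestration: generate or load a system, run every analysis
# module with one configuration, write a reproducible report bundle.

.defaultParams <- function() {
  list(bin_width = 0.5,          # A; density histogram resolution
       d_cut = 3.0,              # A; HB donor-acceptor distance cutoff
       a_cut = 20,               # deg; HB angle cutoff
       extended_acceptors = FALSE,
       cutoff = 12,              # A; LJ/Coulomb pair cutoff
       switch_start = 10,        # A; switching onset
       D_threshold = 2e-6,       # cm^2/s; slow/fast partition boundary
       z_threshold = NULL,       # A; adsorption cutoff (NULL: P peak + 5)
       min_fraction = 0.5,
       segment_start = 0.5,      # diffusion analysis segment
       order_chain = "sn1")
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file with optional blocks \code{synthetic} (arguments
#'   of [membraneSpec()]) or \code{input} (\code{topology},
#'   \code{trajectory} paths), \code{params} (defaults:
#'   [runAll()] documentation), \code{qm} (list of \code{molecule},
#'   \code{energies}, \code{charges}, \code{environment}), \code{seed},
#'   \code{output_dir}.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

.moduleStep <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("module '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a trajectory and executes the density, structure,
#' dynamics, hydrogen-bond and energetics modules — plus reactivity when
#' QM tables are configured — writing per-module TSV/JSON outputs and a
#' top-level \code{report.json} with the configuration echo, seed and
#' package version. Identical configuration and seed give identical
#' outputs. Parameter defaults follow the conventions the analyses are
#' built around: 3 A / 20 deg hydrogen-bond criterion, 12 A pair cutoff
#' with switching from 10 A, 2e-6 cm^2/s diffusion partition boundary,
#' final-sixth-of-run energy frames thinned to at most 100.
#'
#' @param config config list (see [readRunConfig()]) or a YAML path.
#' @return invisibly, the report bundle (list with every module result).
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- if (!is.null(config$seed)) config$seed else 1L
  params <- utils::modifyList(.defaultParams(),
                              config$params %||% list())
  outDir <- config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  traj <- .moduleStep("core_io", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- seed
      generateMembraneTrajectory(do.call(membraneSpec, args))
    } else if (!is.null(config$input)) {
      topo <- readTopologyTable(config$input$topology)
      readTrajectoryTRJ(config$input$trajectory, topo)
    } else {
      .stopf("config needs a 'synthetic' or 'input' block")
    }
  })
  bundle <- list(config = config, seed = seed,
                 package_version = as.character(
                   utils::packageVersion("memtraj")))

  bundle$density <- .moduleStep("density", {
    groups <- intersect(c("P", "choline", "terminal_CH3", "water"),
                        unique(unlist(strsplit(
                          atomTable(traj)$labels, ";", fixed = TRUE))))
    profs <- lapply(groups, computeDensityProfile, traj = traj,
                    binWidth = params$bin_width)
    names(profs) <- groups
    if (length(moleculeIds(traj, "drug"))) {
      profs$drug_com <- computeDensityProfile(traj, "drug",
                                              binWidth = params$bin_width,
                                              useCOM = TRUE)
    }
    for (g in names(profs)) {
      utils::write.table(profs[[g]], file.path(outDir,
                                               paste0("density_", g,
                                                      ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    profs
  })

  bundle$structure <- .moduleStep("structure", {
    rep <- structuralReport(traj)
    ord <- orderParameters(traj, params$order_chain)
    utils::write.table(rep, file.path(outDir, "structure.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ord, file.path(outDir, "order_parameters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(report = rep, order = ord)
  })

  zThr <- params$z_threshold %||% defaultZThreshold(traj)
  bundle$dynamics <- .moduleStep("dynamics", {
    dc <- diffusionCoefficients(traj,
                                segmentStart = params$segment_start)
    dc$location_class <- vapply(dc$molecule_id, function(mid) {
      classifyLocation(traj, mid, zThreshold = zThr,
                       minFraction = params$min_fraction)
    }, character(1))
    part <- partitionByD(stats::setNames(dc$D_cm2_s, dc$molecule_id),
                         params$D_threshold)
    utils::write.table(dc, file.path(outDir, "diffusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(perMolecule = dc, partition = part, z_threshold = zThr)
  })

  bundle$hbonds <- .moduleStep("hbonds", {
    if (!any(labelMask(traj, "donor_H"))) {
      list(byClass = NULL, note = "topology carries no donor_H labels")
    } else {
      hb <- hbondStatistics(traj, dCut = params$d_cut,
                            aCut = params$a_cut,
                            extendedAcceptors =
                              params$extended_acceptors)
      jsonlite::write_json(hb[c("byClass", "totalPerFrame", "nFrames",
                                "nDrugs")],
                           file.path(outDir, "hbonds.json"),
                           auto_unbox = TRUE, digits = NA)
      hb[c("byClass", "totalPerFrame", "nFrames", "nDrugs")]
    }
  })

  bundle$energetics <- .moduleStep("energetics", {
    en <- decomposeDrugLipid(traj, zThreshold = zThr,
                             cutoff = params$cutoff,
                             switchStart = params$switch_start)
    utils::write.table(en$byClass, file.path(outDir, "energy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(en$byMolecule,
                       file.path(outDir, "energy_per_molecule.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    en[c("byClass", "byMolecule")]
  })

  if (!is.null(config$qm)) {
    bundle$reactivity <- .moduleStep("reactivity", {
      res <- lapply(config$qm, function(q) {
        qm <- readQMTables(q$energies, q$charges,
                           molecule = q$molecule %||% "molecule",
                           environment = q$environment %||% "vacuum")
        r <- reactivityDescriptors(qm)
        if (!is.null(r$fukui)) {
          utils::write.table(
            r$fukui,
            file.path(outDir, paste0("fukui_", r$molecule, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
        r[c("molecule", "environment", "I", "A", "mu", "eta")]
      })
      jsonlite::write_json(res, file.path(outDir, "reactivity.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  report <- list(seed = seed, params = params,
                 package_version = bundle$package_version,
                 config = config,
                 summary = list(
                   n_atoms = nAtoms(traj), n_frames = nFrames(traj),
                   n_drugs = length(moleculeIds(traj, "drug")),
                   slow_molecules = bundle$dynamics$partition$slow,
                   fast_molecules = bundle$dynamics$partition$fast))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
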