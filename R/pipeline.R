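#' Pipeline run configuration
#'
#' Collects every input path and tuning parameter of [runPipeline()] into a
#' validated list. The comparison settings encode the longitudinal design: the
#' failing (case) subject is compared against its own baseline timepoint
#' and against the stable (control) subject at the graft-losing timepoint.
#'
#' @param expression,pathways,ppi,seedsDir input file/directory paths.
#' @param outDir output directory for result tables.
#' @param caseSubject,controlSubject subject ids of the failing and stable
#'   subjects.
#' @param graftLossTimepoint,baselineTimepoint timepoint labels of the
#'   graft-losing period and the within-subject baseline.
#' @param alpha GLPAP significance threshold (strict `<`).
#' @param minExpression abundance filter for fold changes.
#' @param nPermutations pathway activation permutations.
#' @param minCrosstalk crosstalk edge threshold.
#' @param restartProb,tol,maxIter,normalization propagation settings.
#' @param nSim random simulations per hypothesis.
#' @param topK top-k coefficient (NULL to skip).
#' @param rngSeed master seed for the run.
#' @return Validated list of class `RunConfig`.
#' @export
runConfig <- function(expression, pathways, ppi, seedsDir, outDir,
                      caseSubject = "case", controlSubject = "control",
                      graftLossTimepoint = "t3", baselineTimepoint = "t2",
                      alpha = 0.05, minExpression = 1,
                      nPermutations = 999, minCrosstalk = 1,
                      restartProb = 0.5, tol = 1e-8, maxIter = 10000,
                      normalization = "symmetric", nSim = 1000,
                      topK = 100, rngSeed = 1) {
    cfg <- as.list(environment())
    if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a RunConfig from a YAML file
#'
#' Field names mirror the arguments of [runConfig()]; unknown fields are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    do.call(runConfig, vals)
}

#' Run the full graft-loss analysis pipeline
#'
#' Executes the stages in study order: score pathway activation in both
#' comparisons, intersect into the GLPAP set, test category enrichment,
#' build the pathway crosstalk network and select above-average central
#' pathways, build the DEG profile, and evaluate the hypothesis seed sets
#' by network propagation. Writes one TSV per stage plus a JSON run
#' manifest (seed, parameters, input/output digests) into `outDir`. Reruns
#' with the same config are deterministic.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return Invisible list with all intermediate results (`activityA`,
#'   `activityB`, `glpaps`, `enrichment`, `graph`, `central`, `deg`,
#'   `hypotheses`).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    cfg <- config
    stage <- function(lab, expr) {
        t0 <- Sys.time()
        out <- tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", lab, conditionMessage(e)), call. = FALSE))
        message(sprintf("[%s] done in %.1fs", lab,
                        as.numeric(Sys.time() - t0, units = "secs")))
        out
    }

    se <- stage("read_expression", readExpression(cfg$expression))
    db <- stage("read_pathways", readPathwayGMT(cfg$pathways))
    ppi <- stage("read_ppi", readPPIEdgeList(cfg$ppi))
    seeds <- stage("read_seeds", readSeedLists(cfg$seedsDir))

    caseLoss <- c(cfg$caseSubject, cfg$graftLossTimepoint)
    caseBase <- c(cfg$caseSubject, cfg$baselineTimepoint)
    ctrlLoss <- c(cfg$controlSubject, cfg$graftLossTimepoint)

    actA <- stage("activity_within", scorePathwayActivity(
        se, db, caseLoss, caseBase,
        label = sprintf("%s_%s_vs_%s", cfg$caseSubject,
                        cfg$graftLossTimepoint, cfg$baselineTimepoint),
        minExpression = cfg$minExpression,
        nPermutations = cfg$nPermutations, rngSeed = cfg$rngSeed))
    actB <- stage("activity_between", scorePathwayActivity(
        se, db, caseLoss, ctrlLoss,
        label = sprintf("%s_vs_%s_%s", cfg$caseSubject,
                        cfg$controlSubject, cfg$graftLossTimepoint),
        minExpression = cfg$minExpression,
        nPermutations = cfg$nPermutations, rngSeed = cfg$rngSeed + 1L))
    glp <- stage("glpap", selectGLPAPs(actA, actB, cfg$alpha))
    enr <- stage("enrichment", enrichCategories(glp, db))
    grph <- stage("network", buildPathwayGraph(glp, db, ppi,
                                               cfg$minCrosstalk))
    central <- stage("central", if (nrow(nodeMetrics(grph)) > 0)
        selectCentralPathways(grph) else
        list(cutoff_closeness = NA_real_, cutoff_degree = NA_real_,
             selected = nodeMetrics(grph)))
    deg <- stage("deg_profile", buildDEGProfile(
        se, caseLoss, ctrlLoss, cfg$minExpression))
    hyp <- stage("hypotheses", evaluateHypotheses(
        ppi, deg, seeds, nSim = cfg$nSim, topK = cfg$topK,
        rngSeed = cfg$rngSeed + 2L, restartProb = cfg$restartProb,
        tol = cfg$tol, maxIter = cfg$maxIter,
        normalization = cfg$normalization))

    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$outDir
    writeTsv(actA, file.path(od, "activity_within.tsv"))
    writeTsv(actB, file.path(od, "activity_between.tsv"))
    glpTab <- data.frame(pathway_id = pathwayIds(glp),
                         name = unname(pathwayNames(db)[pathwayIds(glp)]),
                         category = unname(pathwayCategories(db)[pathwayIds(glp)]))
    writeTsv(glpTab, file.path(od, "glpap.tsv"))
    writeTsv(enr[, c("category", "p_value")],
             file.path(od, "category_enrichment.tsv"))
    writeTsv(crosstalkEdges(grph), file.path(od, "network_edges.tsv"))
    nodeTab <- nodeMetrics(grph)
    nodeTab$selected <- nodeTab$pathway_id %in% central$selected$pathway_id
    writeTsv(nodeTab, file.path(od, "network_nodes.tsv"))
    writeTsv(hypothesisTable(hyp), file.path(od, "hypotheses.tsv"))

    manifest <- list(
        package_version = as.character(utils::packageVersion("glpapnet")),
        rng_seed = cfg$rngSeed,
        parameters = cfg[setdiff(names(cfg), c("expression", "pathways",
                                               "ppi", "seedsDir", "outDir"))],
        inputs = as.list(tools::md5sum(c(cfg$expression, cfg$pathways,
                                         cfg$ppi))),
        outputs = as.list(tools::md5sum(list.files(od, pattern = "\\.tsv$",
                                                   full.names = TRUE))),
        central_cutoffs = list(closeness = central$cutoff_closeness,
                               degree = central$cutoff_degree))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)

    invisible(list(activityA = actA, activityB = actB, glpaps = glp,
                   enrichment = enr, graph = grph, central = central,
                   deg = deg, hypotheses = hyp))
}
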