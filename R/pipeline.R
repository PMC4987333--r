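#' @include synthetic.R nulls.R assembly.R abundance.R utils.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. Either a synthetic
#' `scenario` or the `data` inputs (presence/abundance matrices, trait tables,
#' trees, env tables) must be supplied.
#'
#' @param scenario a [SyntheticScenario-class] (synthetic mode), or NULL.
#' @param data named list with elements presence (or abundance), plantTraits,
#'   orthopteranTraits, plantTree, orthopteranTree, env; used when `scenario`
#'   is NULL.
#' @param seed integer master seed (mandatory).
#' @param alpha,minExpected pair classification parameters.
#' @param nPerm permutations per null (>= 99).
#' @param permMethods permutation algorithms to run side by side.
#' @param null `"adjacency"` or `"matrix"` structure null.
#' @param outDir optional output directory for tables and the JSON report.
#' @return A validated config list of class `"coocnetConfig"`.
#' @export
pipelineConfig <- function(scenario = syntheticScenario(), data = NULL,
                           seed = 1L, alpha = 0.05, minExpected = 1,
                           nPerm = 999,
                           permMethods = c("swap", "tswap", "quasiswap"),
                           null = "adjacency", outDir = NULL) {
  if (nPerm < 99) stop("nPerm must be >= 99 for any reported p-value")
  stopifnot(all(permMethods %in% .permMethods))
  if (is.null(scenario) && is.null(data))
    stop("either a scenario or data inputs are required")
  structure(list(scenario = scenario, data = data, seed = as.integer(seed),
                 alpha = alpha, minExpected = minExpected, nPerm = nPerm,
                 permMethods = permMethods, null = null, outDir = outDir),
            class = "coocnetConfig")
}

.stageLog <- function(stage, t0) {
  message(sprintf("[coocnet] %-28s %7.2fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full co-occurrence assembly-rules pipeline
#'
#' Executes, in order: load/generate -> presence reduction -> exact pairwise
#' classification -> positive network -> greedy modules + nestedness ->
#' structure nulls under every configured permutation method (reported side
#' by side, never mixed) -> knock-out importance -> within-module
#' functional/phylogenetic distance nulls and trait-shift tests per guild ->
#' Hellinger transform -> FDis/PDis dispersion nulls per guild -> per-module
#' and whole-data variance partitioning. Writes CSV tables, a GraphML export
#' and a JSON report when `outDir` is set; rerunning with the same config and
#' seed reproduces every table byte for byte.
#'
#' @param config a `"coocnetConfig"` from [pipelineConfig()].
#' @return The report as a nested list (also serialized to JSON in `outDir`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "coocnetConfig"))
  t0 <- proc.time()[3]
  seed <- config$seed

  if (!is.null(config$scenario)) {
    bundle <- generateBundle(config$scenario, seed = seed)
  } else {
    bundle <- config$data
    if (is.null(bundle$presence))
      bundle$presence <- toPresence(bundle$abundance)
  }
  .stageLog("load/generate", t0)

  presence <- toPresence(bundle$presence)
  guild <- presence@guild
  pairs <- classifyPairs(presence, alpha = config$alpha,
                         minExpected = config$minExpected)
  net <- buildNetwork(pairs, guild = guild)
  retained <- attr(net, "retained")
  .stageLog("pairs + network", t0)

  part <- greedyModules(net)
  nest <- nestedness(net)
  .stageLog("modules + nestedness", t0)

  nulls <- list()
  for (meth in config$permMethods) {
    nulls[[meth]] <- structureSES(
      net, statistic = c("modularity", "nestedness"),
      nPerm = config$nPerm, method = meth, seed = seed + 10L,
      null = config$null, m = presence,
      alpha = config$alpha, minExpected = config$minExpected)
  }
  .stageLog("structure nulls", t0)

  knockout <- knockoutImportance(net)
  .stageLog("knock-out importance", t0)

  traitsByGuild <- list(plant = bundle$plantTraits,
                        orthopteran = bundle$orthopteranTraits)
  treesByGuild <- list(plant = bundle$plantTree,
                       orthopteran = bundle$orthopteranTree)
  assembly <- list(); shifts <- list()
  for (g in .GUILDS) {
    tt <- traitsByGuild[[g]]
    if (is.null(tt)) next
    fd <- functionalDistance(tt)
    rows <- list(multi = moduleDistanceSES(part, fd, guild = g,
                                           guildMap = guild,
                                           nPerm = config$nPerm,
                                           seed = seed + 20L))
    for (tr in colnames(tt@values)) {
      di <- tryCatch(functionalDistance(tt, tr), error = function(e) NULL)
      if (!is.null(di))
        rows[[tr]] <- moduleDistanceSES(part, di, guild = g,
                                        guildMap = guild,
                                        nPerm = config$nPerm,
                                        seed = seed + 21L)
    }
    if (!is.null(treesByGuild[[g]])) {
      pd <- copheneticDistances(treesByGuild[[g]])
      rows$phylogenetic <- moduleDistanceSES(part, pd, guild = g,
                                             guildMap = guild,
                                             nPerm = config$nPerm,
                                             seed = seed + 22L)
    }
    assembly[[g]] <- do.call(rbind, c(
      lapply(names(rows), function(nm)
        cbind(distance = nm, rows[[nm]])), make.row.names = FALSE))
    shifts[[g]] <- tryCatch(
      traitShiftTests(tt, part, guild = g, guildMap = guild),
      error = function(e) data.frame(note = conditionMessage(e)))
  }
  .stageLog("module assembly tests", t0)

  dispersion <- list(); varpart <- list()
  if (!is.null(bundle$abundance)) {
    hel <- hellingerTransform(bundle$abundance)
    for (g in .GUILDS) {
      spG <- names(guild)[guild == g]
      spG <- intersect(spG, colnames(bundle$abundance@values))
      if (length(spG) < 3) next
      mg <- communityMatrix(bundle$abundance@values[, spG, drop = FALSE],
                            guild = guild, valueKind = "abundance")
      if (!is.null(traitsByGuild[[g]])) {
        fd <- functionalDistance(traitsByGuild[[g]])
        if (all(spG %in% rownames(fd@d)))
          dispersion[[paste0(g, "_FDis")]] <-
            dispersionSES(mg, fd, nPerm = config$nPerm, seed = seed + 30L)
      }
      if (!is.null(treesByGuild[[g]])) {
        pd <- copheneticDistances(treesByGuild[[g]])
        if (all(spG %in% rownames(pd@d)))
          dispersion[[paste0(g, "_PDis")]] <-
            dispersionSES(mg, pd, nPerm = config$nPerm, seed = seed + 31L)
      }
    }
    .stageLog("dispersion nulls", t0)

    if (!is.null(bundle$env)) {
      env <- bundle$env
      # whole data ignores network structure; per-module responses are the
      # raw abundance subsets, each Hellinger-transformed on its own so one
      # module's dominance cannot leak into another's composition
      responses <- c(list(whole = hel),
                     lapply(subsetByModule(bundle$abundance, part),
                            function(x) suppressWarnings(
                              hellingerTransform(x))))
      varpart <- lapply(responses, function(h) {
        keep <- rownames(h@values)
        variancePartition(h@values,
                          env@agricultural[keep, , drop = FALSE],
                          env@soil[keep, , drop = FALSE],
                          env@spatial[keep, , drop = FALSE],
                          nPerm = config$nPerm, seed = seed + 40L)
      })
      .stageLog("variance partitioning", t0)
    }
  }

  report <- list(
    provenance = list(seed = seed, alpha = config$alpha,
                      minExpected = config$minExpected,
                      nPerm = config$nPerm,
                      permMethods = config$permMethods,
                      null = config$null,
                      packageVersion =
                        as.character(utils::packageVersion("coocnet"))),
    retained = retained,
    pairCounts = as.list(table(pairs$classification)),
    structure = list(Q = part@Q, nestedness = nest,
                     nModules = nModules(part)),
    nulls = lapply(nulls, function(byStat)
      lapply(byStat, function(x)
        x[c("statistic", "observed", "nPerm", "nullMean", "nullSD",
            "SES", "p", "method")])),
    modules = data.frame(species = names(part@membership),
                         module = as.integer(part@membership),
                         guild = unname(guild[names(part@membership)]),
                         stringsAsFactors = FALSE),
    knockout = knockout,
    assembly = assembly,
    traitShifts = shifts,
    dispersion = lapply(dispersion, function(x)
      x[c("statistic", "observed", "nPerm", "nullMean", "nullSD", "SES",
          "p")]),
    varpart = lapply(varpart, function(x)
      list(fractions = as.list(x$fractions),
           pureTests = x$pureTests)))
  if (!is.null(bundle$truth))
    report$structure$moduleRecovery <- moduleRecovery(part, bundle$truth)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    write.csv(pairs, out("pair_classification.csv"), row.names = FALSE)
    writeNetwork(net, out("network_edges.csv"), out("network.graphml"))
    write.csv(report$modules, out("modules.csv"), row.names = FALSE)
    write.csv(knockout, out("knockout.csv"), row.names = FALSE)
    for (g in names(assembly))
      write.csv(assembly[[g]], out(sprintf("assembly_%s.csv", g)),
                row.names = FALSE)
    for (g in names(shifts))
      write.csv(shifts[[g]], out(sprintf("trait_shifts_%s.csv", g)),
                row.names = FALSE)
    if (length(varpart)) {
      vp <- do.call(rbind, lapply(names(varpart), function(nm)
        data.frame(response = nm, fraction = names(varpart[[nm]]$fractions),
                   adjR2 = unname(varpart[[nm]]$fractions),
                   stringsAsFactors = FALSE)))
      write.csv(vp, out("varpart_fractions.csv"), row.names = FALSE)
    }
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  .stageLog("done", t0)
  report
}
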