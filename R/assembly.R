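#' @include structure.R
NULL

# mean pairwise distance among a set of >= 2 species; NA otherwise
.meanPairDist <- function(D, ids) {
  if (length(ids) < 2) return(NA_real_)
  sub <- D[ids, ids, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Observed mean within-module pairwise distances
#'
#' Mean over all unordered within-module, within-guild species pairs; modules
#' with fewer than two guild species (after intersecting with the distance
#' matrix) are reported as NA (not testable).
#'
#' @param partition a [ModulePartition-class].
#' @param d a [SpeciesDist-class].
#' @param guild optional: restrict to `"plant"` or `"orthopteran"` species
#'   (requires `guildMap`).
#' @param guildMap named character vector species -> guild (e.g.
#'   `guilds(net)`); only needed when `guild` is given.
#' @return Named numeric vector of per-module means.
#' @export
moduleMeanDistance <- function(partition, d, guild = NULL, guildMap = NULL) {
  stopifnot(is(partition, "ModulePartition"), is(d, "SpeciesDist"))
  mem <- partition@membership
  sp <- intersect(names(mem), rownames(d@d))
  if (!is.null(guild)) {
    if (is.null(guildMap)) stop("guild filtering requires guildMap")
    sp <- sp[guildMap[sp] == guild]
  }
  D <- d@d
  mods <- sort(unique(mem))
  vapply(mods, function(k) .meanPairDist(D, sp[mem[sp] == k]), numeric(1)) |>
    setNames(paste0("module", mods))
}

#' Reassignment null for within-module functional/phylogenetic distances
#'
#' Null model: the guild's species are randomly reattributed to the modules,
#' holding every module's size fixed and the distance matrix intact; the mean
#' within-module pairwise distance is recomputed for every module in each
#' draw. Per module: SES = (obs - mean(null)) / sd(null) and the lower-tail
#' p = (1 + #\{null < obs\}) / (1 + nPerm). Low p indicates convergence
#' (distances smaller than chance), high p divergence; with two one-sided
#' reads at alpha each, p <= alpha flags convergence and p >= 1 - alpha
#' divergence.
#'
#' @inheritParams moduleMeanDistance
#' @param nPerm number of reassignment draws (default 9999).
#' @param seed optional integer seed.
#' @return data.frame with one row per module: module, guild, kind, n,
#'   observed, nullMean, nullSD, SES, p, testable.
#' @export
moduleDistanceSES <- function(partition, d, guild = NULL, guildMap = NULL,
                              nPerm = 9999, seed = NULL) {
  stopifnot(is(partition, "ModulePartition"), is(d, "SpeciesDist"))
  if (!is.null(seed)) set.seed(seed)
  mem <- partition@membership
  sp <- intersect(names(mem), rownames(d@d))
  if (!is.null(guild)) {
    if (is.null(guildMap)) stop("guild filtering requires guildMap")
    sp <- sp[guildMap[sp] == guild]
  }
  D <- d@d[sp, sp, drop = FALSE]
  mods <- sort(unique(mem))
  lab <- mem[sp]
  sizes <- vapply(mods, function(k) sum(lab == k), integer(1))
  obs <- vapply(mods, function(k)
    .meanPairDist(D, which(lab == k)), numeric(1))

  nullM <- matrix(NA_real_, nPerm, length(mods))
  idxByMod <- split(seq_along(lab), factor(lab, levels = mods))
  for (i in seq_len(nPerm)) {
    perm <- sample.int(length(lab))
    for (j in seq_along(mods)) {
      ids <- perm[idxByMod[[j]]]
      if (length(ids) >= 2) nullM[i, j] <- .meanPairDist(D, ids)
    }
  }
  mu <- colMeans(nullM)
  sdv <- apply(nullM, 2, sd)
  data.frame(
    module = mods, guild = if (is.null(guild)) "all" else guild,
    kind = d@kind, n = sizes, observed = obs,
    nullMean = mu, nullSD = sdv,
    SES = ifelse(sdv > 0, (obs - mu) / sdv, NA_real_),
    p = vapply(seq_along(mods), function(j) {
      if (is.na(obs[j])) return(NA_real_)
      (1 + sum(nullM[, j] < obs[j])) / (1 + nPerm)
    }, numeric(1)),
    testable = sizes >= 2 & !is.na(sdv) & sdv > 0,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Trait shifts across modules
#'
#' Continuous traits: Kruskal-Wallis rank test across modules. Binary traits:
#' exact test on the module x trait-value contingency table (Fisher's exact
#' test). Raw p-values are reported (no multiplicity correction is applied to
#' the flags); a Benjamini-Hochberg column is added for reference.
#'
#' @param traits a [TraitTable-class].
#' @param partition a [ModulePartition-class].
#' @param guild optional guild filter (requires `guildMap`).
#' @param guildMap named character vector species -> guild.
#' @return data.frame: trait, test (`"kruskal-wallis"`/`"fisher-exact"`),
#'   statistic (KW chi-squared; NA for exact tests), df, p, pBH, note.
#' @export
traitShiftTests <- function(traits, partition, guild = NULL,
                            guildMap = NULL) {
  stopifnot(is(traits, "TraitTable"), is(partition, "ModulePartition"))
  mem <- partition@membership
  sp <- intersect(names(mem), rownames(traits@values))
  if (!is.null(guild)) {
    if (is.null(guildMap)) stop("guild filtering requires guildMap")
    sp <- sp[guildMap[sp] == guild]
  }
  if (length(unique(mem[sp])) < 2)
    stop("need >= 2 modules with guild species")
  out <- lapply(colnames(traits@values), function(tr) {
    x <- traits@values[sp, tr]
    g <- factor(mem[sp])
    ok <- !is.na(x)
    x <- x[ok]; g <- droplevels(g[ok])
    if (length(unique(x)) < 2 || nlevels(g) < 2)
      return(data.frame(trait = tr, test = NA_character_,
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        note = "constant trait or single module; skipped",
                        stringsAsFactors = FALSE))
    if (traits@kind[tr] == "continuous") {
      kt <- kruskal.test(x, g)
      data.frame(trait = tr, test = "kruskal-wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value, note = "",
                 stringsAsFactors = FALSE)
    } else {
      ft <- fisher.test(table(g, x))
      data.frame(trait = tr, test = "fisher-exact", statistic = NA_real_,
                 df = NA_real_, p = ft$p.value, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$pBH <- stats::p.adjust(out$p, method = "BH")
  out
}
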