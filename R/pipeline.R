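## End-to-end pipeline: simulate -> qc -> diffstats -> smooth -> scan ->
## concord -> report, with a YAML-round-trippable configuration and a
## manifest recording seeds, config hash and per-stage row counts.

#' Default pipeline configuration
#'
#' A fully synthetic demonstration setup: a reduced genome of three
#' chromosomes, two breeds at background F_ST 0.1 with a block of loci
#' fixed for alternative alleles around a major (coat-colour-like) QTL,
#' and a three-generation cross (315 F2 + 88 + 98 backcrosses) measured
#' for three traits. Every value can be overridden; [runPipeline()] applies
#' this function's values for anything a user config omits.
#'
#' @param seed global seed; all stages derive child seeds from it.
#' @return Nested list of class `RunConfig`.
#' @export
defaultConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    ## chromosome lengths as a named list so the YAML form keeps the names
    genome = list(chromosomeLengths = list(c1 = 60e6, c2 = 50e6, c3 = 40e6)),
    breeds = list(
      lociPerMb = 10, backgroundFst = 0.1, sampleSizes = c(49L, 20L),
      ancestralFreqRange = c(0.05, 0.95), missingRate = 0.01,
      ## loci fixed for alternative alleles flanking the major QTL
      selected = list(chrom = "c1", center = 30e6, nLoci = 5,
                      spacingBp = 2e5)),
    cross = list(nF1 = 137L, nF2 = 315L, nBC1 = 88L, nBC2 = 98L,
                 nFounders1 = 7L, markerSpacingCM = 15, cmPerMb = 1),
    traits = list(
      list(name = "coatScore", mean = 0, sd = 1,
           qtl = list(chrom = "c1", pos = 30e6, add = 2, dom = 2)),
      list(name = "growth", mean = 0, sd = 1,
           qtl = list(chrom = "c2", pos = 25e6, add = 0.35, dom = 0)),
      list(name = "milkYield", mean = 0, sd = 1, qtl = NULL)),
    qc = list(minMaf = 0.05, maxMissing = 0.10, hweAlpha = 1e-4,
              hweScope = "per-population"),
    tracks = list(binSize = 1e5, window = 11L, tieRule = "up",
                  maMode = "bins"),
    scan = list(gridStep = 1e5),
    thresholds = c(5, 7, 10),
    correlation = list(method = "pearson"),
    topFractions = c(0.01, 0.001)
  ), class = "RunConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' The on-disk representation round-trips losslessly through
#' [yaml::read_yaml()].
#'
#' @param path YAML file path.
#' @param config a `RunConfig` list.
#' @return `readRunConfig`: the configuration list; `writeRunConfig`:
#'   invisibly, `path`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "RunConfig")
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## fill missing entries of cfg from defaults, recursively
mergeConfig <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]]) &&
             !is.null(names(defaults[[nm]])))
      cfg[[nm]] <- mergeConfig(cfg[[nm]], defaults[[nm]])
  }
  cfg
}

## small stable FNV-1a hash of the deparsed config, for the manifest
configHash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

configTraits <- function(cfg) {
  lapply(cfg$traits, function(tr) {
    qtls <- list()
    if (!is.null(tr$qtl) && length(tr$qtl))
      qtls <- list(qtlSpec(tr$qtl$chrom, tr$qtl$pos, tr$qtl$add,
                           tr$qtl$dom %||% 0))
    traitSpec(tr$name, mean = tr$mean %||% 0, sd = tr$sd %||% 1,
              covariateEffects = list(sex = c(male = 0.25, female = -0.25)),
              qtls = qtls)
  })
}

configSelectedLoci <- function(cfg) {
  sel <- cfg$breeds$selected
  if (is.null(sel) || is.null(sel$nLoci) || sel$nLoci < 1) return(NULL)
  off <- (seq_len(sel$nLoci) - (sel$nLoci + 1) / 2) * sel$spacingBp
  data.frame(chrom = sel$chrom, pos = round(sel$center + off),
             p1 = 1, p2 = 0, stringsAsFactors = FALSE)
}

#' Run the full simulate-to-concordance pipeline
#'
#' Executes simulate, qc, diffstats, smooth, scan, concord and report
#' stages in order, writing every stage output as TSV (plus BED for region
#' reports) under `outDir`, together with `manifest.json` recording the
#' config hash, seed and per-stage row counts. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config a `RunConfig` list (see [defaultConfig()]), or a path to
#'   a YAML config file; missing entries are filled from the defaults. An
#'   optional `input` block (`genotypes`, `map`, `format`) loads an
#'   existing two-breed panel instead of simulating one; the cross is
#'   still simulated from the configured design.
#' @param outDir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all in-memory stage results:
#'   `panel`, `qc`, `stats`, `tracks`, `scan`, `aligned`, `correlations`,
#'   `groupMeans`, `tests`, `top`, `study`, `config`, `manifest`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- mergeConfig(config, defaultConfig())
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[diffqtl] ", ...)
  tsv <- function(d, name) {
    write.table(d, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    nrow(d)
  }
  counts <- list()
  seed <- cfg$seed

  ## --- simulate (or load) ----------------------------------------------
  lens <- unlist(cfg$genome$chromosomeLengths)
  if (!is.null(cfg$input$genotypes)) {
    say("load: genotypes from ", cfg$input$genotypes)
    for (p in c(cfg$input$genotypes, cfg$input$map))
      if (!file.exists(p))
        stop("input file does not exist: ", p,
             " (enable simulation by removing the 'input' block)")
    panel <- readGenotypes(cfg$input$genotypes, cfg$input$map,
                           format = cfg$input$format %||% "tsv")
  } else {
    say("simulate: two-breed panel + line cross (seed ", seed, ")")
    nLoci <- round(sum(lens) / 1e6 * cfg$breeds$lociPerMb)
    params <- breedSimParams(
      nLoci, lens, backgroundFst = cfg$breeds$backgroundFst,
      selectedLoci = configSelectedLoci(cfg),
      sampleSizes = unlist(cfg$breeds$sampleSizes),
      ancestralFreqRange = unlist(cfg$breeds$ancestralFreqRange),
      seed = childSeed(seed, "breeds"))
    freqs <- simulateBreedFrequencies(params)
    panel <- sampleGenotypes(freqs, params$sampleSizes,
                             seed = childSeed(seed, "genotypes"),
                             missingRate = cfg$breeds$missingRate)
  }
  writeGenotypes(panel, file.path(outDir, "genotypes.tsv"),
                 file.path(outDir, "map.tsv"))
  counts$genotypes <- nSamples(panel)

  design <- crossDesign(cfg$cross$nF1, cfg$cross$nF2, cfg$cross$nBC1,
                        cfg$cross$nBC2, cfg$cross$nFounders1)
  crossMap <- makeMarkerMap(lens, cfg$cross$markerSpacingCM,
                            cfg$cross$cmPerMb)
  study <- simulateLineCrossStudy(design, crossMap, configTraits(cfg),
                                  seed = childSeed(seed, "cross-study"))
  ph <- cbind(data.frame(id = sampleInfo(study$data)$id,
                         generation = sampleInfo(study$data)$generation),
              phenotypes(study$data), covariates(study$data))
  counts$phenotypes <- tsv(ph, "phenotypes.tsv")
  tsv(markerMap(study$data), "cross_map.tsv")

  ## --- qc ---------------------------------------------------------------
  qc <- applyQc(panel, qcConfig(cfg$qc$minMaf, cfg$qc$maxMissing,
                                cfg$qc$hweAlpha, cfg$qc$hweScope))
  say("qc: removed ", sum(qc$audit$nRemoved), " loci (",
      nLoci(qc$panel), " retained)")
  tsv(qc$audit, "qc_audit.tsv")
  counts$lociAfterQc <- nLoci(qc$panel)

  ## --- diffstats --------------------------------------------------------
  stats <- locusDiffStats(qc$panel)
  stats <- restrictDefinedFst(stats[stats$defined, , drop = FALSE])
  counts$lociDefinedFst <- tsv(
    stats[, c("locus", "chrom", "pos", "p1", "p2", "n1", "n2", "delta",
              "thetaRaw", "fst", "panel")], "locus_stats.tsv")

  ## --- smooth -----------------------------------------------------------
  bs <- cfg$tracks$binSize
  bd <- binTrack(stats, "delta", bs, cfg$tracks$tieRule)
  bf <- binTrack(stats, "fst", bs, cfg$tracks$tieRule)
  md <- movingAverage(bd, cfg$tracks$window, cfg$tracks$maMode, bs)
  mf <- movingAverage(bf, cfg$tracks$window, cfg$tracks$maMode, bs)
  tsv(bd, "binned_delta.tsv"); tsv(bf, "binned_fst.tsv")
  tsv(md, "ma_delta.tsv"); tsv(mf, "ma_fst.tsv")
  counts$bins <- nrow(bd)
  top <- lapply(cfg$topFractions, function(q) topFraction(bd, q))
  names(top) <- paste0("top", cfg$topFractions)
  for (i in seq_along(top))
    writeRegionsBed(top[[i]],
                    file.path(outDir, sprintf("top_delta_%g.bed",
                                              cfg$topFractions[i])),
                    file.path(outDir, sprintf("top_delta_%g.tsv",
                                              cfg$topFractions[i])), bs)

  ## --- scan -------------------------------------------------------------
  say("scan: Haley-Knott regression for ",
      length(traitNames(study$data)), " trait(s)")
  scans <- lapply(traitNames(study$data), function(tr)
    scanTrait(study$data, tr, cfg$scan$gridStep))
  names(scans) <- traitNames(study$data)
  scan <- fMax(scans)
  long <- do.call(rbind, lapply(names(scans), function(tr)
    cbind(trait = tr, scans[[tr]])))
  counts$scanPositions <- nrow(scanGrid(scan))
  tsv(long, "scan.tsv")
  tsv(fmaxTrack(scan), "fmax.tsv")

  ## --- concord ----------------------------------------------------------
  aligned <- alignTracks(scan, bd, bf, md, mf)
  counts$alignedPositions <- tsv(aligned, "aligned.tsv")
  cors <- trackCorrelations(aligned, cfg$correlation$method)
  gm <- thresholdGroupMeans(aligned, cfg$thresholds)
  tests <- concordanceTests(gm)
  tsv(cors, "correlations.tsv")
  tsv(gm, "group_means.tsv")
  tsv(tests, "wilcoxon.tsv")

  manifest <- list(configHash = configHash(cfg), seed = seed,
                   counts = counts,
                   stages = c("simulate", "qc", "diffstats", "smooth",
                              "scan", "concord"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeRunConfig(cfg, file.path(outDir, "config.yaml"))
  say("done: outputs in ", outDir)
  invisible(list(panel = panel, qc = qc, stats = stats,
                 tracks = list(binnedDelta = bd, binnedFst = bf,
                               maDelta = md, maFst = mf),
                 scan = scan, aligned = aligned, correlations = cors,
                 groupMeans = gm, tests = tests, top = top, study = study,
                 config = cfg, manifest = manifest))
}

#' Render figures and summary tables from a pipeline run
#'
#' Produces, per chromosome, an overlay of the Fmax curve and the smoothed
#' delta track (with the chromosome-mean horizontal line), a
#' highF-versus-lowF group-mean scatter per threshold, and a per-chromosome
#' summary table (positions, maxima, correlations). The summary
#' correlations are copied from the concordance stage output, not
#' recomputed.
#'
#' @param run a [runPipeline()] result list, or a run directory containing
#'   its TSV outputs.
#' @param outDir where to write `report_tracks.pdf`,
#'   `report_groups.pdf` and `summary_table.tsv`; defaults to the run
#'   directory when `run` is a path.
#' @return Invisibly, the summary table data.frame.
#' @export
renderReport <- function(run, outDir = NULL) {
  if (is.character(run)) {
    dir <- run
    need <- c("aligned.tsv", "correlations.tsv", "group_means.tsv")
    for (f in need)
      if (!file.exists(file.path(dir, f)))
        stop("missing pipeline output ", f,
             "; run the scan/concord stages first")
    aligned <- read.delim(file.path(dir, "aligned.tsv"))
    cors <- read.delim(file.path(dir, "correlations.tsv"))
    gm <- read.delim(file.path(dir, "group_means.tsv"))
    if (is.null(outDir)) outDir <- dir
  } else {
    aligned <- run$aligned; cors <- run$correlations; gm <- run$groupMeans
    if (is.null(outDir)) stop("outDir is required for in-memory runs")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  empty <- setdiff(unique(cors$chrom), c(unique(aligned$chrom), "genome",
                                         "genome_chrom_mean"))
  if (length(empty))
    message("omitting empty chromosome(s) from plots: ",
            paste(empty, collapse = ", "))

  ## track overlay: Fmax curve + smoothed delta points, per chromosome
  sc <- max(aligned$Fmax) / max(aligned$maDelta, 1e-9)
  p1 <- ggplot2::ggplot(aligned, ggplot2::aes(x = pos / 1e6)) +
    ggplot2::geom_line(ggplot2::aes(y = Fmax), linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(y = maDelta * sc), shape = 18,
                        colour = "steelblue", size = 0.8) +
    ggplot2::geom_hline(
      data = stats::aggregate(maDelta ~ chrom, aligned, mean),
      ggplot2::aes(yintercept = maDelta * sc), linetype = 2,
      colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_y_continuous(
      name = "Fmax",
      sec.axis = ggplot2::sec_axis(~. / sc, name = "MA delta")) +
    ggplot2::labs(x = "position (Mbp)") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(outDir, "report_tracks.pdf"), p1,
                  width = 9, height = 6)

  ## group-mean scatter per threshold
  gmd <- gm[gm$measure == "maDelta" & !is.na(gm$meanLow), , drop = FALSE]
  if (nrow(gmd)) {
    lim <- range(c(gmd$meanHigh, gmd$meanLow))
    p2 <- ggplot2::ggplot(gmd, ggplot2::aes(meanLow, meanHigh)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(shape = 1) +
      ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
      ggplot2::coord_equal(xlim = lim, ylim = lim) +
      ggplot2::labs(x = "mean MA delta, lowF positions",
                    y = "mean MA delta, highF positions") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(outDir, "report_groups.pdf"), p2,
                    width = 8, height = 3.5)
  }

  ## per-chromosome summary (single source of truth: concordance outputs)
  chroms <- unique(aligned$chrom)
  summ <- do.call(rbind, lapply(chroms, function(cn) {
    d <- aligned[aligned$chrom == cn, ]
    rc <- function(m) {
      r <- cors$r[cors$chrom == cn & cors$measure == m]
      if (length(r)) r else NA_real_
    }
    data.frame(chrom = cn, nPositions = nrow(d), maxDelta = max(d$delta),
               maxFst = max(d$fst), maxFmax = max(d$Fmax),
               corFst = rc("fst"), corMaFst = rc("maFst"),
               corDelta = rc("delta"), corMaDelta = rc("maDelta"),
               stringsAsFactors = FALSE)
  }))
  write.table(summ, file.path(outDir, "summary_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(summ)
}
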