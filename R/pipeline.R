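#' @include AllClasses.R io.R diffbind.R classify.R enrichment.R methylation.R loops.R simulate.R
NULL

#' Assemble a pipeline configuration
#'
#' Paths may be omitted when `simulate = TRUE`, in which case the synthetic
#' bundle is generated under `outdir/bundle` first and its files are used as
#' the stage inputs.
#'
#' @param seed mandatory seed, used for the simulation and every resampling
#'   stage.
#' @param outdir output directory.
#' @param simulate generate the synthetic bundle as input (default TRUE).
#' @param simConfig a [SimConfig-class] (defaults to `simConfig(seed)`).
#' @param calls named list of per-condition peak-call BED paths.
#' @param countsPath,samplesPath counts matrix and sample sheet TSVs.
#' @param methylationPath single-CpG methylation TSV.
#' @param cgiPath CpG-island BED.
#' @param loopsPath BEDPE of loops.
#' @param matrixPath,binsPath dense contact matrix TSV and bins BED.
#' @param geneModelPath optional gene model TSV (see [readGeneModel()]);
#'   when given, the classification table gains genomic-context and
#'   nearest-gene columns.
#' @param genomePath optional genome FASTA; when given (or simulated), a
#'   per-class GC-content summary is written.
#' @param lfcMin,padjMax classifier thresholds (defaults 1.5 and 0.005).
#' @param resampleN resampling draws (default 1000).
#' @param apaW APA window half-width in bins (default 5).
#' @param promoterHalfwidth promoter annotation window (default 2000).
#' @return A validated configuration list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed, outdir, simulate = TRUE, simConfig = NULL,
                           calls = NULL, countsPath = NULL, samplesPath = NULL,
                           methylationPath = NULL, cgiPath = NULL,
                           loopsPath = NULL, matrixPath = NULL, binsPath = NULL,
                           geneModelPath = NULL, genomePath = NULL,
                           lfcMin = 1.5, padjMax = 0.005, resampleN = 1000L,
                           apaW = 5L, promoterHalfwidth = 2000) {
    if (missing(seed)) stop("a seed is required")
    stopifnot(lfcMin > 0, padjMax > 0, padjMax < 1, resampleN >= 1, apaW >= 1)
    cfg <- list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
                simConfig = simConfig, calls = calls, countsPath = countsPath,
                samplesPath = samplesPath, methylationPath = methylationPath,
                cgiPath = cgiPath, loopsPath = loopsPath,
                matrixPath = matrixPath, binsPath = binsPath,
                geneModelPath = geneModelPath, genomePath = genomePath,
                lfcMin = lfcMin, padjMax = padjMax,
                resampleN = as.integer(resampleN), apaW = as.integer(apaW),
                promoterHalfwidth = promoterHalfwidth)
    class(cfg) <- "pipelineConfig"
    cfg
}

.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    cfg <- config
    cfg$outdir <- NULL  # hash the analysis parameters, not the destination
    writeLines(deparse(cfg[order(names(cfg))]), tmp)
    unname(tools::md5sum(tmp))
}

.stamp <- function(config) {
    sprintf("nucleatR %s | seed %d | config %s",
            as.character(utils::packageVersion("nucleatR")),
            config$seed, .configHash(config))
}

.requirePath <- function(path, what) {
    if (is.null(path) || !file.exists(path))
        stop("required input for stage '", what, "' not found: ",
             if (is.null(path)) "(not configured)" else path)
    path
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (optional) -> diffbind (union, counts, size factors,
#' dispersions, both Wald contrasts) -> classify (labels, widths, interpeak
#' distances) -> enrich (CGI overlap Fisher + resampling) -> cgi (island
#' methylation calls, enrichment by status) -> loops (anchor classes, span
#' ANOVA, APA, per-chromosome summary). All outputs are TSV/BED files under
#' `config$outdir`, each carrying a header comment with the tool version and
#' config hash, plus a `manifest.tsv` with per-stage row counts and seeds.
#' Runs are idempotent: the same config and seed give byte-identical output.
#'
#' @param config a [pipelineConfig()] list.
#' @return (Invisibly) a list with the principal in-memory results.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- .stamp(config)
    manifest <- list()
    note <- function(stage, rows, seed = NA_integer_)
        manifest[[length(manifest) + 1L]] <<- data.frame(
            stage = stage, rows = rows, seed = seed)
    fp <- function(x) file.path(outdir, x)
    runStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## --- simulate -----------------------------------------------------------
    bundleDir <- file.path(outdir, "bundle")
    if (isTRUE(config$simulate)) {
        runStage("simulate", {
            sc <- if (is.null(config$simConfig)) simConfig(config$seed)
                  else config$simConfig
            simulateBundle(sc, bundleDir)
        })
        config$calls <- as.list(stats::setNames(
            file.path(bundleDir, paste0("calls_", CONDITIONS, ".bed")), CONDITIONS))
        config$countsPath <- file.path(bundleDir, "counts.tsv")
        config$samplesPath <- file.path(bundleDir, "samples.tsv")
        config$methylationPath <- file.path(bundleDir, "methylation.tsv")
        config$cgiPath <- file.path(bundleDir, "cgi.bed")
        config$loopsPath <- file.path(bundleDir, "loops.bedpe")
        config$matrixPath <- file.path(bundleDir, "matrix_chr1.tsv")
        config$binsPath <- file.path(bundleDir, "bins_chr1.bed")
        config$genomePath <- file.path(bundleDir, "genome.fa")
        note("simulate", length(list.files(bundleDir)), config$seed)
    }

    ## --- diffbind -----------------------------------------------------------
    diffb <- runStage("diffbind", {
        calls <- lapply(CONDITIONS, function(cond)
            readPeakBed(.requirePath(config$calls[[cond]], "diffbind")))
        names(calls) <- CONDITIONS
        union <- mergeUnion(calls)
        pe <- readCountsTable(.requirePath(config$countsPath, "diffbind"),
                              .requirePath(config$samplesPath, "diffbind"))
        if (nrow(pe) != length(union))
            stop("counts matrix rows do not match the union peak set")
        SummarizedExperiment::rowRanges(pe) <- stats::setNames(union, rownames(pe))
        pe <- estimateSizeFactors(pe)
        pe <- estimateDispersions(pe)
        c1 <- waldContrast(pe, "steady_state", "auxin")
        c2 <- waldContrast(pe, "auxin", "reintroduction")
        writeContrastResults(c1, fp("contrast_auxin_vs_steady_state.tsv"), stamp)
        writeContrastResults(c2, fp("contrast_reintroduction_vs_auxin.tsv"), stamp)
        list(union = union, calls = calls, pe = pe, c1 = c1, c2 = c2)
    })
    note("diffbind", length(diffb$union))

    ## --- classify -----------------------------------------------------------
    cls <- runStage("classify", {
        presence <- flagPresence(diffb$union, diffb$calls)
        classified <- classifyPeaks(diffb$union, presence, diffb$c1, diffb$c2,
                                    classifierThresholds(config$lfcMin,
                                                         config$padjMax))
        df <- data.frame(peak = names(classified),
                         chrom = as.character(GenomicRanges::seqnames(classified)),
                         start = start(classified) - 1L, end = end(classified),
                         as.data.frame(mcols(classified)))
        if (!is.null(config$geneModelPath)) {
            genes <- readGeneModel(.requirePath(config$geneModelPath, "classify"))
            df$context <- annotateGenomicContext(
                classified, genes, promoterHalfwidth = config$promoterHalfwidth)
            ng <- nearestGene(classified, genes)
            df$nearest_gene <- ng$gene_id
            df$tss_distance <- ng$distance
        }
        con <- file(fp("classification.tsv"), "w")
        writeLines(paste0("# ", stamp), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        for (cl in c("nucleation", "control_exclusive", "persistent")) {
            sub <- classified[classified$label == cl]
            mcols(sub) <- NULL
            writePeakBed(sub, fp(paste0(cl, ".bed")), header = stamp)
        }
        ws <- widthStats(classified)
        con <- file(fp("width_stats.tsv"), "w")
        writeLines(paste0("# ", stamp), con)
        utils::write.table(ws, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        if (!is.null(config$genomePath)) {
            genome <- Biostrings::readDNAStringSet(
                .requirePath(config$genomePath, "classify"))
            names(genome) <- sub("\\s.*", "", names(genome))
            gc <- regionGC(genome, classified)
            gcDf <- do.call(rbind, lapply(levels(classified$label), function(cl) {
                v <- gc[classified$label == cl]
                data.frame(class = cl, n = sum(!is.na(v)),
                           mean_gc = if (any(!is.na(v))) mean(v, na.rm = TRUE)
                                     else NA_real_)
            }))
            con <- file(fp("gc_content.tsv"), "w")
            writeLines(paste0("# ", stamp), con)
            utils::write.table(gcDf, con, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            close(con)
        }
        classified
    })
    note("classify", length(cls))

    nucleation <- cls[cls$label == "nucleation"]
    controlEx <- cls[cls$label == "control_exclusive"]

    ## --- enrich + cgi -------------------------------------------------------
    cgiRes <- runStage("cgi", {
        meth <- readMethylationTable(.requirePath(config$methylationPath, "cgi"))
        cgi <- readPeakBed(.requirePath(config$cgiPath, "cgi"))
        islandCalls <- suppressWarnings(callIslandStatus(cgi, meth))
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(islandCalls)),
                         start = start(islandCalls) - 1L, end = end(islandCalls),
                         as.data.frame(mcols(islandCalls)[c("n_cpg", "n_meth",
                                                            "frac_meth", "status")]))
        con <- file(fp("island_calls.tsv"), "w")
        writeLines(paste0("# ", stamp), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        enr <- cgiEnrichment(nucleation, controlEx, islandCalls,
                             N = config$resampleN, seed = config$seed)
        fish <- lapply(c(unmethylated = "unmethylated", methylated = "methylated"),
                       function(st) fisherOverlap(nucleation, controlEx,
                                                  islandCalls[!is.na(islandCalls$status) &
                                                              islandCalls$status == st]))
        rep <- do.call(rbind, lapply(names(enr), function(st) {
            r <- enr[[st]]
            data.frame(feature = paste0("cgi_", st), observed = r@observed,
                       expected = r@expected, oe_ratio = r@oeRatio,
                       p_empirical = r@pEmpirical, fisher_p = fish[[st]]$p,
                       odds_ratio = fish[[st]]$oddsRatio, N = r@N, seed = r@seed)
        }))
        con <- file(fp("enrichment.tsv"), "w")
        writeLines(paste0("# ", stamp), con)
        utils::write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        list(islandCalls = islandCalls, enrichment = enr, fisher = fish)
    })
    note("enrich", 2L, config$seed)
    note("cgi", length(cgiRes$islandCalls))

    ## --- loops --------------------------------------------------------------
    loopRes <- runStage("loops", {
        loops <- readBedpe(.requirePath(config$loopsPath, "loops"))
        loops <- classifyLoopAnchors(loops, nucleation)
        ss <- spanStats(loops)
        cm <- readContactMatrix(.requirePath(config$matrixPath, "loops"),
                                .requirePath(config$binsPath, "loops"))
        apaRes <- apa(loops, cm, w = config$apaW)
        sumDf <- loopSummaryByChrom(loops)
        con <- file(fp("loop_summary.tsv"), "w")
        writeLines(c(paste0("# ", stamp),
                     sprintf("# ANOVA F = %.6g (df %d/%d), p = %.6g",
                             ss$F, ss$df[1], ss$df[2], ss$p),
                     sprintf("# APA score = %.6g over %d loops (%d excluded)",
                             apaScore(apaRes), apaRes@nLoops, apaRes@nExcluded)), con)
        utils::write.table(sumDf, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        list(loops = loops, spanStats = ss, apa = apaRes)
    })
    note("loops", length(loopRes$loops))

    mdf <- do.call(rbind, manifest)
    con <- file(fp("manifest.tsv"), "w")
    writeLines(paste0("# ", stamp), con)
    utils::write.table(mdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)

    invisible(list(classified = cls, contrast1 = diffb$c1, contrast2 = diffb$c2,
                   islandCalls = cgiRes$islandCalls,
                   cgiEnrichment = cgiRes$enrichment,
                   cgiFisher = cgiRes$fisher,
                   loops = loopRes$loops, spanStats = loopRes$spanStats,
                   apa = loopRes$apa, manifest = mdf))
}
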