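#' Run the full panel-evaluation pipeline
#'
#' Executes every analysis stage on a genotype dataset — allele
#' frequencies, per-locus forensic parameters and cumulative indices,
#' Hardy-Weinberg and LD screens, the full-sibling LR power study,
#' pairwise FST and DA matrices, informativeness for assignment, AMOVA,
#' individual- and population-level PCA, classical MDS, an NJ tree, and
#' (when several continents are present) the biogeographic-origin
#' classifiers — writing tabular/JSON/PHYLIP/Newick outputs under
#' \code{outDir} plus a manifest of seeds, parameters, versions and
#' per-stage status. A failed stage is recorded in the manifest and later
#' independent stages still run. Inputs are never mutated; all outputs
#' are pure functions of (input, config, seed).
#'
#' @param g a \linkS4class{DipGenotypes} object, or the path of a
#'   genotype table readable by \code{\link{readGenotypeTable}}.
#' @param outDir output directory (created if needed).
#' @param seed integer master seed for every stochastic stage.
#' @param config optional list of overrides: \code{population} (focal
#'   population for forensic/HWE/LD/kinship stages; default the most
#'   sampled one), \code{nPairs}, \code{limits}, \code{ldPermutations},
#'   \code{models}, \code{split}.
#' @return The manifest (a list), invisibly; also written as
#'   \code{manifest.json} in \code{outDir}.
#' @export
runAll <- function(g, outDir, seed = 1L, config = list()) {
    if (is.character(g)) g <- readGenotypeTable(g)
    stopifnot(is(g, "DipGenotypes"))
    if (ncol(g) == 0L || nrow(g) == 0L) stop("empty genotype input")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfg <- utils::modifyList(
        list(population = names(sort(table(populationLabels(g)),
                                     decreasing = TRUE))[1],
             nPairs = 1000L, limits = c(1, 10, 100, 1000, 10000),
             ldPermutations = 0L, models = c("rf", "xgb", "svm", "dt"),
             split = 0.75),
        config)
    gtPath <- file.path(outDir, "genotypes.tsv")
    writeGenotypeTable(g, gtPath)
    manifest <- list(seed = as.integer(seed), parameters = cfg,
                     input_md5 = unname(tools::md5sum(gtPath)),
                     r_version = R.version.string,
                     package_version =
                         as.character(utils::packageVersion("dipkit")),
                     stages = list())
    env <- new.env()
    stage <- function(name, out, fun) {
        res <- tryCatch({
            value <- fun()
            manifest$stages[[name]] <<- list(status = "ok", outputs = out)
            value
        }, error = function(e) {
            manifest$stages[[name]] <<- list(status = "failed",
                                             message = conditionMessage(e))
            NULL
        })
        assign(name, res, envir = env)
        res
    }
    pf <- function(...) file.path(outDir, ...)

    stage("frequencies", "frequencies.tsv", function() {
        f <- alleleFrequencies(g)
        writeFrequencyTable(f, pf("frequencies.tsv"))
        f
    })
    stage("forensic", c("forensic_stats.tsv", "cumulative.json"), function() {
        st <- locusForensicStats(g, population = cfg$population)
        utils::write.table(st, pf("forensic_stats.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        cum <- panelCumulative(st)
        writeResultsJson(cum, pf("cumulative.json"))
        list(stats = st, cumulative = cum)
    })
    stage("hwe", "hwe.tsv", function() {
        h <- hweTest(g, population = cfg$population)
        utils::write.table(h, pf("hwe.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        h
    })
    stage("ld", "ld.tsv", function() {
        l <- ldScreen(g, population = cfg$population,
                      permutations = cfg$ldPermutations, seed = seed)
        utils::write.table(l, pf("ld.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        l
    })
    stage("kinship", c("kinship_power.tsv", "kinship_lr_samples.tsv"),
          function() {
        f <- get("frequencies", envir = env)
        if (is.null(f)) stop("frequency stage failed")
        pop <- if (cfg$population %in% colnames(pIns(f))) cfg$population
               else colnames(pIns(f))[1]
        ks <- powerStudy(f, population = pop, nPairs = cfg$nPairs,
                         limits = cfg$limits, seed = seed)
        utils::write.table(kinshipSummary(ks), pf("kinship_power.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(hypothesis = rep(c("full_sibling", "unrelated"),
                                        each = ks@nPairs),
                       log10_lr = c(ks@log10FS, ks@log10UN)),
            pf("kinship_lr_samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        ks
    })
    multiPop <- length(unique(populationLabels(g))) > 1
    if (multiPop) {
        stage("fst", "fst.phylip", function() {
            fst <- fstMatrix(g)
            writePhylipDistance(fst, pf("fst.phylip"), relaxedNames = TRUE)
            fst
        })
        stage("da", "da.phylip", function() {
            f <- get("frequencies", envir = env)
            if (is.null(f)) stop("frequency stage failed")
            da <- daMatrix(f)
            writePhylipDistance(da, pf("da.phylip"), relaxedNames = TRUE)
            da
        })
        stage("informativeness", "informativeness.tsv", function() {
            f <- get("frequencies", envir = env)
            if (is.null(f)) stop("frequency stage failed")
            tab <- informativenessIn(f)
            utils::write.table(tab, pf("informativeness.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            tab
        })
        stage("amova", "amova.json", function() {
            a <- amova(g)
            writeResultsJson(a, pf("amova.json"))
            a
        })
        stage("mds", "mds.tsv", function() {
            fst <- get("fst", envir = env)
            if (is.null(fst)) stop("fst stage failed")
            mds <- classicalMds(clampNonNegative(fst))
            utils::write.table(data.frame(label = rownames(mds$points),
                                          mds$points),
                               pf("mds.tsv"), sep = "\t", quote = FALSE,
                               row.names = FALSE)
            mds
        })
        if (length(unique(populationLabels(g))) >= 3)
            stage("nj_tree", "nj.nwk", function() {
                fst <- get("fst", envir = env)
                if (is.null(fst)) stop("fst stage failed")
                tr <- njTree(clampNonNegative(fst))
                writeNewick(tr, pf("nj.nwk"))
                tr
            })
        stage("pca_population", "pca_population.tsv", function() {
            f <- get("frequencies", envir = env)
            if (is.null(f)) stop("frequency stage failed")
            pc <- dipPca(f)
            utils::write.table(
                data.frame(label = rownames(pc$coordinates),
                           pc$coordinates),
                pf("pca_population.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            pc
        })
    }
    stage("pca_individual", "pca_individual.tsv", function() {
        pc <- dipPca(g)
        utils::write.table(data.frame(sample = rownames(pc$coordinates),
                                      pc$coordinates),
                           pf("pca_individual.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        pc
    })
    if (length(unique(continentLabels(g))) >= 2)
        stage("classifier", "classifier.json", function() {
            ce <- trainEval(g, models = cfg$models, split = cfg$split,
                            seed = seed)
            writeResultsJson(
                lapply(ce, function(x)
                    list(model = x$model,
                         confusion = as.data.frame(x$confusion),
                         stats = x$stats)),
                pf("classifier.json"))
            ce
        })
    writeResultsJson(manifest, pf("manifest.json"))
    invisible(manifest)
}
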