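#' Accuracy with exact binomial confidence interval
#'
#' Overall accuracy of a confusion matrix (trace over total) with the
#' Clopper-Pearson exact binomial confidence interval computed from beta
#' quantiles.
#'
#' @param cm square confusion matrix of non-negative integer counts
#'   (rows = predicted, columns = truth).
#' @param level confidence level (default 0.95).
#' @return A list with \code{accuracy}, \code{lower}, \code{upper},
#'   \code{level}, \code{method}, \code{correct} and \code{total}.
#' @examples
#' accuracyCi(matrix(c(9, 1, 0, 10), 2, 2))
#' @export
accuracyCi <- function(cm, level = 0.95) {
    cm <- as.matrix(cm)
    stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
    n <- sum(cm)
    if (n < 1) stop("empty confusion matrix")
    x <- sum(diag(cm))
    alpha <- 1 - level
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    list(accuracy = x / n, lower = lower, upper = upper, level = level,
         method = "Clopper-Pearson", correct = x, total = n)
}

#' Train and evaluate biogeographic-origin classifiers
#'
#' Fits any of four classifiers (random forest, gradient-boosted trees,
#' support vector machine, decision tree) to predict each sample's
#' continent label from its insertion dosages, using a stratified holdout
#' split, and scores the holdout with a confusion matrix (predicted x
#' truth) and exact binomial accuracy CI. Hyperparameters are the
#' libraries' defaults; missing dosages are mean-imputed per locus.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param models character subset of \code{c("rf", "xgb", "svm", "dt")}.
#' @param split training fraction of the stratified holdout split
#'   (default 0.75).
#' @param seed integer seed controlling the split and every stochastic
#'   fit.
#' @param classes which label to predict: \code{"continent"} (default) or
#'   \code{"population"}.
#' @return A named list, one entry per model, each with
#'   \code{confusion} (predicted x truth integer matrix), \code{stats}
#'   (the \code{\link{accuracyCi}} list) and \code{model} name; plus an
#'   attribute \code{"split"} recording holdout sizes and the seed.
#' @export
trainEval <- function(g, models = c("rf", "xgb", "svm", "dt"),
                      split = 0.75, seed = 1L,
                      classes = c("continent", "population")) {
    classes <- match.arg(classes)
    models <- match.arg(models, several.ok = TRUE)
    ga <- autosomal(g)
    X <- .meanImpute(t(dosage(ga)))
    y <- factor(if (classes == "continent") continentLabels(ga)
                else populationLabels(ga))
    if (nlevels(y) < 2) stop("need at least two classes")
    set.seed(as.integer(seed))
    trainIdx <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(split * length(idx))))
    }), use.names = FALSE)
    testIdx <- setdiff(seq_along(y), trainIdx)
    if (!length(testIdx)) stop("holdout is empty; lower `split`")
    if (nlevels(droplevels(y[trainIdx])) < nlevels(y))
        stop("a class is absent from training; increase data or split")
    xtr <- X[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]
    xte <- X[testIdx, , drop = FALSE]; yte <- y[testIdx]
    fitters <- list(
        rf = function() {
            fit <- randomForest::randomForest(xtr, ytr)
            stats::predict(fit, xte)
        },
        xgb = function() {
            fit <- xgboost::xgboost(
                data = xtr, label = as.integer(ytr) - 1L,
                objective = "multi:softmax", num_class = nlevels(y),
                nrounds = 50, verbose = 0, nthread = 1)
            factor(levels(y)[stats::predict(fit, xte) + 1L], levels = levels(y))
        },
        svm = function() {
            fit <- e1071::svm(xtr, ytr)
            stats::predict(fit, xte)
        },
        dt = function() {
            df <- data.frame(y = ytr, xtr, check.names = FALSE)
            fit <- rpart::rpart(y ~ ., data = df, method = "class")
            stats::predict(fit, data.frame(xte, check.names = FALSE),
                           type = "class")
        })
    out <- lapply(models, function(mname) {
        set.seed(as.integer(seed))
        pred <- factor(fitters[[mname]](), levels = levels(y))
        cm <- table(predicted = pred, truth = yte)
        cm <- matrix(as.integer(cm), nlevels(y), nlevels(y),
                     dimnames = list(predicted = levels(y),
                                     truth = levels(y)))
        list(model = mname, confusion = cm, stats = accuracyCi(cm))
    })
    names(out) <- models
    attr(out, "split") <- list(n_train = length(trainIdx),
                               n_test = length(testIdx),
                               fraction = split, seed = as.integer(seed))
    out
}
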