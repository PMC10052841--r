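#' Per-locus forensic parameters for biallelic DIP loci
#'
#' Closed-form forensic parameters used to characterise every locus of a
#' DIP identification panel:
#' \itemize{
#'   \item \code{unbiasedHe}: unbiased expected heterozygosity
#'     \eqn{2pq \cdot 2n/(2n-1)} (Nei's small-sample correction);
#'   \item \code{picBiallelic}: polymorphism information content
#'     \eqn{1-(p^2+q^2)-2p^2q^2};
#'   \item \code{matchProbability}: match probability from the
#'     \emph{observed} genotype frequencies,
#'     \eqn{MP=\sum_g (c_g/n)^2}, and its complement the power of
#'     discrimination \eqn{PD = 1-MP};
#'   \item \code{peTrio}: trio power of exclusion
#'     \eqn{h^2(1-2hH^2)} with \eqn{h} the observed heterozygosity and
#'     \eqn{H = 1-h};
#'   \item \code{tpi}: typical paternity index \eqn{1/(2H)}.
#' }
#'
#' @param p insertion-allele frequency in [0, 1].
#' @param n diploid sample size (\eqn{\ge 2}).
#' @return A numeric vector (vectorised over the first argument).
#' @examples
#' unbiasedHe(0.7146, 233)   # 0.4088 at 4 dp
#' picBiallelic(0.5)         # 0.375 exactly
#' @export
unbiasedHe <- function(p, n) {
    stopifnot(all(p >= 0 & p <= 1))
    if (any(n < 2)) stop("n must be at least 2")
    2 * p * (1 - p) * 2 * n / (2 * n - 1)
}

#' @rdname unbiasedHe
#' @export
picBiallelic <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    q <- 1 - p
    1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' @rdname unbiasedHe
#' @param counts integer vector of genotype counts (any length \eqn{\ge 1};
#'   for a biallelic locus the three dosage classes).
#' @export
matchProbability <- function(counts) {
    counts <- as.numeric(counts)
    total <- sum(counts)
    if (length(counts) == 0L || total < 1) stop("empty genotype counts")
    mp <- sum((counts / total)^2)
    c(MP = mp, PD = 1 - mp)
}

#' @rdname unbiasedHe
#' @param ho observed heterozygosity in [0, 1].
#' @export
peTrio <- function(ho) {
    stopifnot(all(ho >= 0 & ho <= 1))
    H <- 1 - ho
    ho^2 * (1 - 2 * ho * H^2)
}

#' @rdname unbiasedHe
#' @export
tpi <- function(ho) {
    stopifnot(all(ho >= 0 & ho <= 1))
    out <- ifelse(ho == 1, Inf, 1 / (2 * (1 - ho)))
    if (any(ho == 1))
        warning("Ho = 1: typical paternity index is infinite")
    out
}

#' Forensic parameter table for a genotyped panel
#'
#' Computes, per autosomal locus, the seven standard forensic parameters
#' (Ho, He, PIC, MP, PD, PE, TPI) from observed genotype counts.
#' Allele frequencies feed He and PIC; MP/PD come from observed genotype
#' frequencies; PE and TPI are functions of observed heterozygosity.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param population optional population label(s) to subset to.
#' @return A data.frame, one row per locus, columns \code{locus},
#'   \code{n}, \code{p_ins}, \code{Ho}, \code{He}, \code{PIC}, \code{MP},
#'   \code{PD}, \code{PE}, \code{TPI}.
#' @export
locusForensicStats <- function(g, population = NULL) {
    cc <- genotypeCounts(g, population = population)
    n <- cc$n0 + cc$n1 + cc$n2
    if (any(n < 2)) stop("need at least 2 genotyped samples per locus")
    p <- (2 * cc$n2 + cc$n1) / (2 * n)
    ho <- cc$n1 / n
    mp <- (cc$n0^2 + cc$n1^2 + cc$n2^2) / n^2
    data.frame(locus = cc$locus, n = n, p_ins = p, Ho = ho,
               He = unbiasedHe(p, n), PIC = picBiallelic(p),
               MP = mp, PD = 1 - mp, PE = peTrio(ho),
               TPI = ifelse(ho == 1, Inf, 1 / (2 * (1 - ho))),
               row.names = NULL)
}

#' Panel-wide cumulative forensic indices
#'
#' Combines per-locus match probabilities and exclusion powers into the
#' cumulative match probability \eqn{CMP = \prod_l MP_l}, cumulative power
#' of discrimination \eqn{CPD = 1 - CMP} and cumulative power of exclusion
#' \eqn{CPE = 1 - \prod_l (1 - PE_l)}. Products are accumulated in log
#' space; the many-nines decimal expansion of CPD (which double precision
#' cannot represent) is produced by digit-string arithmetic from the
#' log-space mantissa/exponent form.
#'
#' @param stats a data.frame with columns \code{MP} and \code{PE}, as
#'   returned by \code{\link{locusForensicStats}}.
#' @param digits significant digits of the CMP mantissa used in the
#'   formatted strings.
#' @return A list with \code{log10CMP}, \code{CMP}, \code{CMPString}
#'   (scientific, e.g. \code{"2.7029E-24"}), \code{CPD}, \code{CPDString}
#'   (full decimal expansion), and \code{CPE}.
#' @examples
#' panelCumulative(data.frame(MP = c(0.4, 0.5), PE = c(0.25, 0.25)))
#' @export
panelCumulative <- function(stats, digits = 5L) {
    stopifnot(all(c("MP", "PE") %in% names(stats)), nrow(stats) >= 1L)
    mp <- stats$MP
    pe <- stats$PE
    stopifnot(all(mp >= 0 & mp <= 1), all(pe >= 0 & pe <= 1))
    if (any(mp == 0)) {
        warning("a locus has MP = 0; CMP is 0")
        log10cmp <- -Inf
    } else log10cmp <- sum(log10(mp))
    cpe <- -expm1(sum(log1p(-pe)))
    cmp <- 10^log10cmp
    list(log10CMP = log10cmp,
         CMP = cmp,
         CMPString = .mantissaExpString(log10cmp, digits),
         CPD = 1 - cmp,
         CPDString = .oneMinusString(log10cmp, digits),
         CPE = cpe)
}

## log10x -> "m.mmmmE-e" with `digits` significant digits of the mantissa
.mantissaExpString <- function(log10x, digits = 5L) {
    if (!is.finite(log10x)) return("0")
    e <- floor(log10x)
    m <- 10^(log10x - e)
    m <- round(m, digits - 1L)
    if (m >= 10) { m <- m / 10; e <- e + 1L }
    sprintf("%.*fE%d", digits - 1L, m, e)
}

## Exact decimal expansion of 1 - x for tiny x given log10(x): digit-string
## subtraction 10^D - s, avoiding any floating-point representation of 1 - x.
.oneMinusString <- function(log10x, digits = 5L) {
    if (!is.finite(log10x)) return("1")
    if (log10x >= 0) stop("argument must be below 1")
    e <- floor(log10x)
    m <- 10^(log10x - e)
    s <- round(m * 10^(digits - 1L))
    if (s >= 10^digits) { s <- s / 10; e <- e + 1L }
    D <- -e + digits - 1L           # total decimal places
    tail <- sprintf("%0*.0f", digits, 10^digits - s)
    ## 10^D - s = (D-digits nines) then (10^digits - s); drop trailing zeros
    out <- paste0("0.", strrep("9", D - digits), tail)
    sub("0+$", "", out)
}
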