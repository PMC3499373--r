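# Readers and writers for the plain-text interchange formats: genotype
# TSV (rows = individuals, columns = sites, integer minor-allele
# counts), minimal biallelic VCF, phenotype TSV (id, y1, y2, cov_*),
# result and residual TSVs, and YAML/JSON run configuration.

#' Write genotypes to TSV
#'
#' First column \code{id}, remaining columns one per site (header =
#' site ids), integer minor-allele counts.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param path output file.
#' @param ids optional individual ids (default \code{ind1, ind2, ...}).
#' @export
writeGenotypesTsv <- function(G, path, ids = NULL) {
    cnt <- genotypeCounts(G)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(cnt)))
    df <- data.frame(id = ids, cnt, check.names = FALSE)
    colnames(df) <- c("id", siteInfo(G)$site_id)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read genotypes from TSV
#'
#' @param path file written by \code{\link{writeGenotypesTsv}} (or
#'   compatible). Site MAF is set to the empirical frequency.
#' @return a \code{\linkS4class{GenotypeMatrix}}; individual ids are
#'   kept as row names of the count matrix.
#' @export
readGenotypesTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "id")
        stop("genotype TSV must start with an 'id' column")
    cnt <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(cnt))) stop("missing genotype values in ", path)
    storage.mode(cnt) <- "integer"
    rownames(cnt) <- df$id
    GenotypeMatrix(cnt)
}

#' Write a minimal biallelic VCF
#'
#' Synthetic coordinates (chromosome 1, positions 100, 200, ...),
#' REF/ALT A/C with ALT the minor allele, GT-only FORMAT, unphased
#' diploid genotypes.
#'
#' @inheritParams writeGenotypesTsv
#' @export
writeGenotypesVcf <- function(G, path, ids = NULL) {
    cnt <- genotypeCounts(G)
    n <- nrow(cnt)
    if (is.null(ids)) ids <- paste0("ind", seq_len(n))
    gtStrings <- c("0/0", "0/1", "1/1")
    lines <- c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", ids), collapse = "\t"))
    body <- vapply(seq_len(ncol(cnt)), function(j) {
        paste(c("1", 100 * j, siteInfo(G)$site_id[j], "A", "C", ".",
                "PASS", ".", "GT", gtStrings[cnt[, j] + 1L]),
              collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
    invisible(path)
}

#' Read genotypes from a VCF
#'
#' Biallelic records with GT fields; multiallelic records and missing
#' genotypes are rejected (no imputation). Sites are oriented to the
#' minor allele: when the alternate-allele frequency exceeds 0.5 the
#' counts are flipped, so the stored MAF never exceeds 0.5.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
readGenotypesVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
        stop("multiallelic records not supported: ",
             paste(fix[multi, "ID"], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    missing <- is.na(gt) | gt %in% c("./.", ".|.", ".")
    if (any(missing)) {
        bad <- unique(rownames(gt)[which(missing, arr.ind = TRUE)[, 1]])
        stop("missing genotypes at: ", paste(bad, collapse = ", "))
    }
    alt <- matrix(
        vapply(strsplit(gt, "[/|]"),
               function(a) sum(a == "1"), integer(1)),
        nrow = nrow(gt), dimnames = dimnames(gt))
    cnt <- t(alt)                         # individuals x sites
    f <- colMeans(cnt) / 2
    flip <- f > 0.5
    cnt[, flip] <- 2L - cnt[, flip]
    storage.mode(cnt) <- "integer"
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
        paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    colnames(cnt) <- ids
    GenotypeMatrix(cnt)
}

#' Read a phenotype table
#'
#' Tab-separated with mandatory columns \code{id}, \code{y1}, \code{y2}
#' and optional covariates \code{cov_*}; missing values are an error.
#'
#' @param path phenotype TSV.
#' @return \code{data.frame} with \code{id}, \code{y1}, \code{y2} and
#'   covariate columns.
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    for (col in c("id", "y1", "y2"))
        if (!col %in% names(df))
            stop("phenotype file lacks required column '", col, "'")
    if (anyNA(df))
        stop("missing values in phenotype file ", path)
    df
}

#' Align phenotypes with a genotype matrix by id
#'
#' Explicit inner join on \code{id}; any mismatch is an error reporting
#' the counts on each side.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}} with individual ids as
#'   count-matrix row names.
#' @param phenotypes a \code{data.frame} from
#'   \code{\link{readPhenotypes}}.
#' @return list with \code{G} and \code{phenotypes} in matching order.
#' @export
alignCohort <- function(G, phenotypes) {
    gids <- rownames(genotypeCounts(G))
    if (is.null(gids)) stop("genotype matrix carries no individual ids")
    common <- intersect(gids, phenotypes$id)
    if (length(common) != length(gids) ||
        length(common) != nrow(phenotypes))
        stop(sprintf(
            "id mismatch: %d genotype ids, %d phenotype ids, %d shared",
            length(gids), nrow(phenotypes), length(common)))
    list(G = G[match(common, gids), ],
         phenotypes = phenotypes[match(common, phenotypes$id), ,
                                 drop = FALSE])
}

#' Write region-test results
#'
#' One row per (region, test) with statistic and p-value columns.
#'
#' @param results \code{data.frame} from \code{\link{regionTests}}
#'   (optionally with a \code{region} column prepended).
#' @param path output TSV.
#' @export
writeResults <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write null-model residuals
#'
#' @param fit a \code{\linkS4class{NullFit}} (or numeric residuals).
#' @param path output TSV with columns \code{id}, \code{residual}.
#' @param ids optional individual ids.
#' @export
writeResiduals <- function(fit, path, ids = NULL) {
    e <- if (is(fit, "NullFit")) residuals(fit) else fit
    if (is.null(ids)) ids <- paste0("ind", seq_along(e))
    utils::write.table(data.frame(id = ids, residual = e), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a run configuration
#'
#' YAML (\code{.yml}/\code{.yaml}) or JSON file with blocks
#' \code{genotypes}, \code{traits}, \code{ascertainment}, \code{tests}.
#'
#' @param path configuration file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else
        jsonlite::fromJSON(path, simplifyVector = TRUE)
}
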