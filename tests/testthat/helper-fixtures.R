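# Tiny VCF fixture builders (written programmatically at test time).

vcfFixture <- function(samples, rows, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,",
                  "Description=\"Functional annotations\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r) {
    info <- if (!is.null(r$ann) && nzchar(r$ann)) paste0("ANN=", r$ann)
            else "."
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".",
            r$filter %||% "PASS", info, "GT", r$gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simpleManifest <- function(samples, roles, populations = NULL) {
  CohortManifest(samples, roles,
                 populations %||% rep("pop", length(samples)))
}

# A hand-built VariantTable with explicit genotype codes.
tableFromCodes <- function(geno, ann = NULL, qual = NULL, chrom = NULL,
                           pos = NULL) {
  n <- nrow(geno)
  v <- data.frame(
    chrom = chrom %||% rep("1", n),
    pos = pos %||% seq(1000L, by = 1000L, length.out = n),
    ref = rep("A", n), alt = rep("G", n),
    qual_label = qual %||% rep("PASS", n),
    ann = ann %||% rep(annPool()[2], n),
    stringsAsFactors = FALSE)
  VariantTable(v, geno, c("1", "2"))
}
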