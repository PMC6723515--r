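#!/usr/bin/env Rscript
## Optional one-time helper: download the deposited sea urchin records used
## by the accession-based checks into inst/extdata/accessions/. The package
## and its tests never download anything themselves; run this once on a
## machine with network access if you want those checks to run.
##
##   Rscript scripts/fetch_accessions.R [dest_dir]

dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else "inst/extdata/accessions"
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

efetch <- function(ids, path) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
                "db=nuccore&rettype=fasta&retmode=text&id=",
                paste(ids, collapse = ","))
  download.file(url, path, quiet = TRUE)
  message("wrote ", path)
  Sys.sleep(0.5)  # NCBI rate courtesy
}

## S. intermedius ND6 sample (five S, four L variants)
efetch(sprintf("KY9642%02d.1", 90:98), file.path(dest, "si_nd6.fasta"))
## M. nudus ND6 sample (two S, fourteen L, one +2-residue variant)
efetch(sprintf("AB8630%02d.1", 97:99) |> c(sprintf("AB8631%02d.1", 0:12)),
       file.path(dest, "mn_nd6.fasta"))
## the two complete S. intermedius mitochondrial genomes (15,705 bp each)
efetch(c("KY964299.1", "KY964300.1"), file.path(dest, "si_genomes.fasta"))
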