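# Shared replicate study at generator defaults (seeds 1..20), computed
# once and reused by the acceptance-level property tests.

.replicate_cache <- new.env(parent = emptyenv())

replicate_study <- function(n_reps = 20) {
  key <- paste0("reps", n_reps)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])

  genotypes <- c("WT", "R1", "R2", "R1R2")
  platforms <- c("microarray", "rnaseq")
  out <- list(planted_sig = NULL, precision = NULL, jaccard = NULL,
              meta_z = list(microarray = NULL, rnaseq = NULL))
  for (seed in seq_len(n_reps)) {
    run <- suppressWarnings(run_pipeline(list(seed = seed)))
    planted <- run$data$truth$planted_pathways$pathway

    # planted-pathway significance at the strongest genotype's contrast
    for (platform in platforms) {
      enr <- run$contrasts[[paste0("R1R2__DIO__", platform)]]$enrichment
      out$planted_sig <- c(out$planted_sig,
                           enr$combined$significant[
                             enr$combined$pathway %in% planted])
    }

    out$precision <- rbind(out$precision,
                           unlist(run$summary$precision_at_k))
    out$jaccard <- rbind(out$jaccard, do.call(rbind, run$concordance))
    for (platform in platforms) {
      mz <- vapply(genotypes, function(geno) {
        s <- run$profiles[[paste0(geno, "__DIO__", platform)]]$systems
        s$meta_z[s$id == run$data$truth$planted_system]
      }, 0)
      out$meta_z[[platform]] <- rbind(out$meta_z[[platform]], mz)
    }
  }
  .replicate_cache[[key]] <- out
  out
}
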