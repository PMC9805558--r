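# Lazily-built fixtures shared across test files within one run. Builders
# are deterministic (fixed seeds), so cached and fresh results are
# identical.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# three species, two genomes each (rep + 1% diverged strain)
fx_collection <- function() {
  fixture("collection", function() {
    sim_collection(tempfile("fxcol"), n_species = 3L, genomes_per_species = 2L,
                   genome_length = 10000L, strain_divergence = 0.01, seed = 7L)
  })
}

fx_db <- function() {
  fixture("db", function() {
    build_db(parse_toc(fx_collection()$toc), out_dir = tempfile("fxdb"))
  })
}

# the population-SNV study cohort: 2 strains, 10 samples, 100 planted sites
fx_cohort <- function() {
  fixture("cohort", function() sim_two_strain_cohort(seed = 101L))
}

# a small on-disk end-to-end scenario: 2 species, 2 samples with FASTQs
fx_pipeline_scenario <- function() {
  fixture("pipeline_scenario", function() {
    dir <- tempfile("pipe")
    col <- sim_collection(file.path(dir, "collection"), n_species = 2L,
                          genomes_per_species = 1L, genome_length = 8000L,
                          n_genes = 20L, seed = 501L)
    covs <- list(sample1 = c(s01 = 15, s02 = 6), sample2 = c(s01 = 8, s02 = 12))
    samples <- list()
    for (sid in names(covs)) {
      r1 <- NULL; r2 <- NULL
      for (sp in names(covs[[sid]])) {
        sim <- simulate_reads(
          list(list(strain_id = paste0(sid, ".", sp),
                    seq = col$truth[[sp]]$seq, proportion = 1)),
          coverage = covs[[sid]][[sp]], error_rate = 0.001,
          seed = sub_seed_helper(502L, sid, sp))
        r1 <- rbind(r1, sim$r1); r2 <- rbind(r2, sim$r2)
      }
      p1 <- file.path(dir, paste0(sid, "_R1.fq"))
      p2 <- file.path(dir, paste0(sid, "_R2.fq"))
      write_fastq(r1, p1); write_fastq(r2, p2)
      samples[[length(samples) + 1L]] <- list(sample_id = sid, r1 = p1, r2 = p2)
    }
    list(dir = dir, toc = col$toc, samples = samples, truth = col$truth)
  })
}

sub_seed_helper <- function(seed, sid, sp) {
  (seed + 131L * utf8ToInt(substr(sid, nchar(sid), nchar(sid))) +
     17L * utf8ToInt(substr(sp, nchar(sp), nchar(sp)))) %% 2147483647L
}

fx_pipeline_run <- function() {
  fixture("pipeline_run1", function() {
    sc <- fx_pipeline_scenario()
    out <- file.path(sc$dir, "run1")
    cfg <- list(db = list(toc = sc$toc), samples = sc$samples, out = out)
    suppressMessages(res <- run_pipeline(cfg))
    list(config = cfg, result = res, out = out)
  })
}
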