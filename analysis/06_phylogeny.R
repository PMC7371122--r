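#!/usr/bin/env Rscript
# The enzyme-family phylogeny workflow on simulated anchor protein
# sequences: redundancy reduction by greedy identity clustering at 0.9,
# up to five representatives per cluster, trimming and concatenation of two
# domain alignment blocks, neighbor joining on p-distances and midpoint
# rooting. Also applies the N50 >= 50 kb assembly quality filter to the
# simulated assemblies.

suppressPackageStartupMessages(library(fesmgc))

seed <- 301L
params <- mgc_params()

ss <- generate_sequence_set(n = 40, n_families = 4, within_identity = 0.95,
                            between_identity = 0.5, length = 300, seed = seed)
cl <- greedy_identity_cluster(ss$sequences, min_identity = params$min_identity)
cl <- select_representatives(cl, k = params$max_representatives, seed = seed)
reps <- unlist(lapply(cl$representative_ids, function(x) strsplit(x, ",")[[1]]))
message(sprintf("%d sequences -> %d identity clusters -> %d representatives.",
                length(ss$sequences), nrow(cl), length(reps)))

# treat the first/second halves of each sequence as the two domain blocks
# (simulated sequences are ungapped, hence trivially aligned)
aln <- ss$sequences[reps]
block1 <- Biostrings::subseq(aln, 1, 150)
block2 <- Biostrings::subseq(aln, 151, 300)
t1 <- trim_alignment(block1, params$max_gap_fraction)
t2 <- trim_alignment(block2, params$max_gap_fraction)
merged <- concatenate_alignments(t1, t2)
message(sprintf("Merged alignment: %d sequences x %d columns.",
                length(merged), Biostrings::width(merged)[1]))

d <- alignment_distances(merged, correction = "p")
tree <- midpoint_root(nj_tree(d))
write_newick(tree, file.path("results", "representatives_tree.nwk"))

# do representative trees keep planted families monophyletic?
fam_of <- setNames(ss$truth$family, ss$truth$seq_id)
mono <- vapply(unique(fam_of[reps]), function(f) {
  tips <- reps[fam_of[reps] == f]
  length(tips) < 2 || ape::is.monophyletic(tree, tips)
}, logical(1))
message(sprintf("Planted families monophyletic in the rooted tree: %d of %d.",
                sum(mono), length(mono)))

# assembly quality filter on the simulated genomes
simdir <- file.path("results", "simulation")
genomes <- lapply(list.files(simdir, pattern = "\\.gff3$", full.names = TRUE),
                  read_genome_annotation, format = "gff3")
lengths <- lapply(genomes, function(g) unname(g$contig_lengths))
names(lengths) <- vapply(genomes, `[[`, character(1), "genome_id")
qc <- n50_filter(lengths, threshold = params$n50_min)
write.table(qc, file.path("results", "assembly_n50.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("N50 filter at %d bp: %d of %d assemblies pass (median N50 %.0f bp).",
                params$n50_min, sum(qc$pass), nrow(qc), median(qc$n50)))
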