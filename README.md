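# levitax

Taxonomic classification of bacteria-infecting positive-sense
single-stranded RNA viruses (class *Leviviricetes* — the MS2/Qbeta
lineage) from genome assemblies.

Metatranscriptomic surveys recover thousands of contigs from these
phages. `levitax` implements the quantitative decision ladder behind
their modern (ICTV 2021) taxonomy, for anyone who needs to place new
contigs into it or rebuild its machinery from scratch:

1. **Class** — the genome encodes the three core proteins (maturation
   protein MP, coat protein CP, RNA-directed RNA polymerase RdRP), found
   by ORF calling and profile-HMM scanning; it is *coding-complete* when
   MP ≥ 350 aa and RdRP ≥ 500 aa.
2. **Order** — RdRP cluster membership: RdRP_A → *Norzivirales*,
   RdRP_B → *Timlovirales*.
3. **Family** — CP cluster membership via the packaged cluster→taxon map
   (nine CP clusters, six families). A CP whose family belongs to a
   different order than the RdRP implies leaves **both** ranks
   `Unassigned` (the incongruence rule).
4. **Genus / species** — pairwise amino-acid identity (PAAI) of the
   RdRP, single-linkage at **50 %** (genus) and **80 %** (species), with
   exemplar selection by archival priority.

The toolkit includes a Plan7-style profile-HMM engine (build, Viterbi and
forward bit scores, HMMER3 ASCII I/O), Markov clustering of all-vs-all
Smith–Waterman similarity graphs for regenerating cluster libraries,
Needleman–Wunsch PAAI with a terminal-gap-exclusion denominator,
neighbor-joining trees with clade-concordance reports, and a synthetic
genome simulator with planted taxonomy that makes the whole chain
testable offline. See the methods vignette
(`vignettes/levitax-methods.Rmd`) for the model details and design
choices.

## Worked example

Simulate a small reference set with planted taxonomy, build its profile
library, and classify the genomes against it:

```r
library(levitax)

sim <- simulate_reference_set(n_orders = 2, families_per_order = 1,
                              genera_per_family = 2, species_per_genus = 2,
                              members_per_species = 2, seed = 7)
lib <- build_profile_library(sim$msas)

rd  <- sim$proteins[sim$proteins$role == "RdRP", ]
ref <- data.frame(id = rd$id, sequence = rd$sequence,
                  genus_id   = sim$truth$genus_id,
                  species_id = sim$truth$species_id)

calls <- classify_genomes(sim$genomes, lib, ref,
                          demarcation_config(cluster_taxon_map = sim$map))
calls
#> levitax calls: 16 genomes, 16 coding-complete, 0 incongruent
#>          genome_id complete   order     family  genus_id    species_id
#> 1  lv_o1f1g01s01m1     TRUE Order_1 Family_1_1 g_o1f1_01 g_o1f1_01_s01
#> 2  lv_o1f1g01s01m2     TRUE Order_1 Family_1_1 g_o1f1_01 g_o1f1_01_s01
#> 3  lv_o1f1g01s02m1     TRUE Order_1 Family_1_1 g_o1f1_01 g_o1f1_01_s02
#> 4  lv_o1f1g01s02m2     TRUE Order_1 Family_1_1 g_o1f1_01 g_o1f1_01_s02
#> 5  lv_o1f1g02s01m1     TRUE Order_1 Family_1_1 g_o1f1_02 g_o1f1_02_s01
#> 6  lv_o1f1g02s01m2     TRUE Order_1 Family_1_1 g_o1f1_02 g_o1f1_02_s01
#> 7  lv_o1f1g02s02m1     TRUE Order_1 Family_1_1 g_o1f1_02 g_o1f1_02_s02
#> 8  lv_o1f1g02s02m2     TRUE Order_1 Family_1_1 g_o1f1_02 g_o1f1_02_s02
#> 9  lv_o2f1g01s01m1     TRUE Order_2 Family_2_1 g_o2f1_01 g_o2f1_01_s01
#> 10 lv_o2f1g01s01m2     TRUE Order_2 Family_2_1 g_o2f1_01 g_o2f1_01_s01
#> ...
```

Every genome is coding-complete (the planted MP/RdRP are 400/540 aa),
each RdRP cluster resolves to its order, each CP cluster to its family,
and the PAAI ladder returns each genome's planted genus and species.

Real data goes through the same functions: `read_fasta()` your contigs,
`read_hmmer3()` a profile library (your own, or one built with
`build_profile()`/the `build-hmms` subcommand), keep the packaged ICTV
map (`default_cluster_taxon_map()`), and call `classify_genomes()`. A
shell interface wrapping the same functions ships in
`inst/scripts/levitax`:

```sh
levitax classify --genomes contigs.fasta --hmms lib.hmm \
    --reference ref_rdrp.faa --reference-taxa ref_taxa.tsv --out calls.tsv
```

Demarcation alone, from a protein set:

```r
m <- paai_matrix(setNames(rd$sequence, rd$id))
demarcate(m, genus_threshold = 50, species_threshold = 80)
#> PAAI demarcation: 4 genera (>= 50%), 8 species (>= 80%), 16 sequences
```

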