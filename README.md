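# haploscope

Haplotype-resolved analysis of a focal germline risk allele in a small
cancer cohort, with structural-variant junction chemistry and the
germline/somatic filter cascades such studies apply. The motivating
setting is a rare kidney cancer associated with sickle cell trait: the
risk allele (HbS analogue) is examined at *haplotype* resolution — did
it arise on one founder haplotype or several ancestral backgrounds, and
is it the causal variant or a passenger in linkage disequilibrium?

The package is aimed at cancer/population-genetics analysts working
with phased (e.g. linked-read) genomes of small cohorts plus a labeled
reference panel.

## What it computes

**Haplotype blocks.** Phased VCF calls (`GT` with `|`, `PS` phase sets,
`PQ` phase quality) are assembled into per-sample haplotype blocks
(calls with `PQ >= 23` by default), with broken blocks stitched across
a matched sample of the same patient by majority allele agreement.

**Haplotype PCA.** Mutant (focal-allele-carrying) and wild-type
haplotypes over a ±100 kb window, restricted to panel-represented
sites, are encoded as 0/1 vectors and decomposed jointly with the panel
by centered SVD; population assignment is by nearest panel centroid.

**Fine-mapping.** For each site, carriers are counted on mutant vs
wild-type haplotype blocks, giving a table (a, b; c, d), and tested
with the one-sided Fisher exact test

&nbsp;&nbsp;&nbsp;&nbsp;p = P(X ≥ a),&nbsp; X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b),

computed in log space. A perfectly separating site over 14 diploid
cases (a = 14, d = 14) gives p = 1/C(28,14) = 2.49 × 10⁻⁸.

**SV junctions.** Each assembled fusion contig is split-enumerated
against its two reference flanks: k bp of microhomology ⇔ k + 1
equivalent junction placements; an unexplained middle segment is an
untemplated insertion; blunt joins have a unique placement. Breakpoints
are annotated against repeat/gene BED tracks (half-open point overlap),
homologous gene pairs scored by global-alignment percent identity, and
fusion-transcript orientation called with GT/AG splice-site flags.

**Filters.** Panel-of-normals (site in ≥ 2 normals), VAF > 10%,
≥ 6 variant reads, population AF ≤ 0.1% for somatic calls; disruptive
consequence + candidate gene + AF < 0.1% for germline candidates — each
call audited with the rule that removed it. Plus kataegis detection
(≥ 6 SNVs, inter-mutation distance ≤ 1 kb), compound risk-allele
genotyping, carrier-enrichment statistics and chrX:chrY sex inference.

**Synthetic data.** A first-class simulation module generates every
input with known truth: a Balding–Nichols three-population panel with
identity-by-descent cores around the focal allele, SV truth sets with
designed junction chemistry, somatic call sets with planted artifacts
and kataegis, and a serialized fixture bundle (VCF/FASTA/BED/TSV with a
checksum manifest).

## Worked example

```r
library(haploscope)

# simulate the study design: 3 populations, 137 trait-carrier pairs,
# 200-kb window, IBD cores around the focal allele at 100 kb
panel <- inject_ibd_core(simulate_panel(panel_sim_config(seed = 1)))
panel
#> Simulated phased panel: 274 haplotypes (137 carriers), 400 sites in a
#> 200000-bp window; focal allele at 100000

# fine-map using a 14-case cohort (one mutant + one wild-type haplotype each)
ch    <- cohort_individuals(panel, 14)
sites <- panel$sites$position
vec <- function(row, label)
  structure(list(haplotype_id = rownames(panel$haplotypes)[row],
                 site_index = sites, values = panel$haplotypes[row, ],
                 label = label, origin = "cohort",
                 population = panel$population_label[row]),
            class = "haplotype_vector")
res <- fine_map_region(lapply(2*ch - 1, vec, "mutant"),
                       lapply(2*ch,     vec, "wild_type"))
res$site[1]; res$p[1]
#> [1] 1e+05
#> [1] 2.492734e-08
```

The focal allele at position 100,000 ranks first with
p = 2.49 × 10⁻⁸ — the probability that all 14 carrier haplotypes land
on the mutant side of the 28-haplotype cohort by chance. Running the
junction classifier over a designed truth set:

```r
svt <- simulate_sv_truth(simulate_reference(seed = 1), 10, seed = 2)
r <- svt$records[1, ]
classify_junction(r$left_flank, r$right_flank, r$contig_seq)
#> Junction: microhomology (3 bp), splits [15, 18]
```

The 3-bp microhomology makes four junction placements equivalent
(splits 15–18 of the contig); the designed class is recovered exactly.

An end-to-end run (`run_pipeline(run_config(out_dir = "out", seed = 1))`)
simulates a fixture bundle, extracts cohort haplotypes from the phased
VCF, performs the joint PCA, fine-maps the window, classifies and
annotates SV junctions, and applies the somatic filter cascade, writing
per-stage TSVs and a checksummed manifest; re-running with the same
seed reproduces the manifest byte-for-byte. A thin command-line
wrapper over these functions is installed at
`inst/scripts/haploscope.R`.

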