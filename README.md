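# retroburst

Annotation and evolutionary dynamics of LTR retrotransposon families.

Large flatworm (and many other metazoan) genomes carry recently expanded
families of LTR retrotransposons. Characterizing one family means answering
three questions from raw contigs and copy alignments:

1. **Where are the full-unit elements?** A genuine insertion is a pair of
   long terminal repeats (LTRs, here starting `TGT` and ending `ACA`)
   flanked by identical 4-bp target site duplications (TSDs). LTR-pair
   identity dates each insertion, and the primer binding site (PBS) just
   inside the 5'-LTR identifies the tRNA that primes reverse transcription.
2. **How do the copies group?** Consensus elements, ORF prediction, and
   single-linkage clustering at the conventional 70% identity threshold for
   family designation.
3. **How are the copies evolving?** Substitution-saturation screening
   (entropy index Iss against simulated critical values Iss.c), F84 and
   p-distances with bootstrap SEs, Tajima's D and Fu & Li's D/F (negative
   values are the signature of a recent transposition burst), uncorrected
   counting dN/dS on the 1311-bp RT (DNA/RNA polymerase domain) codon
   region with Mann-Whitney group comparisons, sliding-window divergence
   screens for recombination, and NJ + bootstrap trees with
   monophyly/paraphyly classification of copy groups (paraphyly marks
   master-lineage succession).

Every stage is testable without downloads through a burst simulator
(`make_template`, `simulate_expansion`) that emits host contigs, ground
truth, genealogy and the true copy alignment under a master-lineage model
with purifying selection.

The core statistic for selection is the *counting* dN/dS: for each codon
pair, synonymous and nonsynonymous steps are averaged over all minimal
mutational pathways avoiding stop codons (Nei-Gojobori pathway
convention), gap/stop codons are removed pairwise, and the ratio `nd/sd`
is left uncorrected for multiple hits and site counts -- appropriate for
heavily disrupted retrotransposon ORFs where model-based estimators
cannot be fit.

## Worked example

```r
library(retroburst)

# 1. simulate a recent burst of one family into host contigs
tpl <- make_template(seed = 1)                     # 4.9 kb unit, 300 bp LTRs
ev  <- evo_params(burst_schedule = list(c(0, 8)), mu_h = 1e-3, end_time = 10)
sim <- simulate_expansion(tpl, n_contigs = 3, contig_len = 60000,
                          evo = ev, seed = 1)
head(sim$truth[, c("copy_id", "contig_id", "start", "end", "strand", "tsd")])
#>   copy_id contig_id start   end strand  tsd
#> 1 copy001  contig01 72230 77130      + CCTT
#> 2 copy002  contig01 33546 38446      - TCCA
#> 3 copy003  contig01 48058 52958      + AACG
#> 4 copy004  contig01 53148 58048      + CATC
#> 5 copy005  contig02 21936 26836      - AGCC
#> 6 copy006  contig02 49877 54777      - TGCT

# 2. recover the elements from the raw contigs
seeds <- data.frame(contig = sim$truth$contig_id,
                    start  = (sim$truth$start + sim$truth$end) %/% 2,
                    end    = (sim$truth$start + sim$truth$end) %/% 2 + 1)
ann <- annotate_genome(sim$contigs, seeds)
ann$elements[1:3, c("contig", "start", "end", "strand", "tsd",
                    "tsd_confirmed", "ltr_identity")]
#>     contig start   end strand  tsd tsd_confirmed ltr_identity
#> 1 contig01 72230 77130      + CCTT          TRUE    0.9600000
#> 2 contig01 33546 38446      + TCCA          TRUE    0.9833333
#> 3 contig01 48058 52958      + AACG          TRUE    0.9733333
```

All 8 boundaries and TSDs match the truth table exactly; LTR-pair
identities of 96-99% reflect the ten time-units of post-insertion decay at
`mu_h = 1e-3` (the strand call for copy002 is wrong -- strand is read from
ORF orientation, which degrades for decayed copies; boundaries and TSDs
are strand-symmetric and unaffected).

```r
# 3. burst signature: excess of rare variants among the copies
td <- tajimas_d(sim$aligned)
c(D = td$D, p = td$p_beta)
#>           D           p
#> -1.77679271  0.01998902
```

A significantly negative Tajima's D from a star-like burst genealogy --
the same signature the neutrality tests show on real retrotransposon copy
sets -- without any population-genetic selection.

```r
# 4. selection-strength recovery on a 1311-bp RT codon region
rt_seq <- substr(template_full_seq(tpl), tpl$rt_interval[1] + 1,
                 tpl$rt_interval[2])
sel <- simulate_codon_family(rt_seq, n = 12, subs_per_copy = 40,
                             omega = 0.1, seed = 2)
fd <- family_dnds(sel, groups = setNames(rep("master", 12),
                                         names(sel$seqs)))
fd$groups[, c("group", "n_pairs", "median", "q1", "q3")]
#>    group n_pairs    median        q1        q3
#> 1 master      66 0.2240803 0.1666667 0.3057692
```

Copies simulated under purifying selection (`omega = 0.1`) give a median
counting dN/dS far below the neutral mutational-opportunity ratio of this
ORF (about 2.6 under the transition-biased process), i.e. the generator's
selection strength is recovered by the statistic.

## Command line

```sh
rbd simulate --seed 1 --out-dir out --families 2 --copies 10
rbd annotate --genome out/genome.fasta --seeds out/truth.bed --out-dir out
rbd stats    --alignment out/fam1_aligned.fasta --out-dir out
rbd all      --seed 1 --out-dir out        # chain everything
```

Global flags: `--config` (flat `key = value` file), `--seed`, `--out-dir`,
`--log-level`. See `?run_pipeline` for the per-stage inputs and artifacts.

## Documentation

`vignettes/retroburst-methods.Rmd` documents the models, defaults,
numerical choices and limitations.
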