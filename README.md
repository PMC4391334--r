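# methylaudit

Privacy auditing of DNA methylation array data.

Genome-wide methylation matrices (Illumina HumanMethylation450 and kin) are
deposited in open repositories on the assumption that, unlike genotyping
arrays, they carry no individually identifying information. That assumption
fails. A CpG-destroying SNP — a C→A/G/T substitution at the assayed cytosine,
written here as the "D" allele — abolishes the methylation signal from the
affected chromosome. At a CpG that is normally fully methylated, the beta
value β ∈ [0,1] (the fraction of methylated signal) then reads out genotype
directly:

| genotype | expected β |
|----------|-----------|
| CC       | ≈ 1.0     |
| CD       | ≈ 0.5     |
| DD       | ≈ 0.0     |

Scanning a probes × samples beta matrix for tri-modal probes therefore
recovers hard genotypes, and on the order of a thousand such loci are enough
to build a unique genetic fingerprint of every "anonymous" donor — while the
same array also reports substance-use signals such as smoking via AHRR
cg05575921 hypomethylation. `methylaudit` is for data depositors, repository
curators, and IRBs who want to measure and remediate that risk before (or
after) sharing.

## The audit

For each probe, beta values are binned by strict thresholds
(X: β > 0.7 → CC; Y: 0.3 < β < 0.7 → CD; Z: β < 0.25 → DD; everything else
unbinned). A probe is a candidate when at least ⌈0.95·n⌉ of its n samples
fall in the three bins and both homozygote bins hold ≥ 4 observations.
Candidates are converted to genotype counts (n_CC, n_CD, n_DD) and screened
by a Pearson χ² (1 df) Hardy-Weinberg equilibrium test; probes with HWE
P > 0.01 are retained and ranked by observed heterozygosity H_obs = n_CD/n.
Identification evidence uses the forensic product rule under HWE: the random
match probability of a profile is Π over loci of the genotype frequency
(f_C², 2·f_C·f_D, or f_D²), reported as log10. Remediation is redaction —
removal of the informative rows.

## Worked example

```r
library(methylaudit)
sim   <- simulate_dataset(simulation_config(n_snp_probes = 300,
                                            n_background_probes = 3000,
                                            seed = 20))
audit <- run_audit(sim$beta)
#> audit: 206 informative probe(s) retained from 3301 assayed
top_k(audit$summaries, 5)
#>   probe_id n_cc n_cd n_dd n_missing       maf   het_obs   het_exp hwe_chi2      hwe_p
#> 1  snp0270   19   65   27         0 0.4639640 0.5855856 0.4974028 3.488784 0.06178596
#> 2  snp0095   34   64   13         0 0.4054054 0.5765766 0.4821037 4.262418 0.03896442
#> 3  snp0082   28   62   21         0 0.4684685 0.5585586 0.4980115 1.640703 0.20022906
#> 4  snp0134   33   62   16         0 0.4234234 0.5585586 0.4882721 2.300081 0.12936726
#> 5  snp0220   29   62   20         0 0.4594595 0.5585586 0.4967129 1.720799 0.18959026
```

Of 3,301 probes, 206 survive the bin-occupancy and HWE screens — all of them
planted SNP probes, none of the 3,000 non-genetic background probes. Each row
gives the genotype counts across the 111 simulated samples, the minor allele
frequency, observed vs HWE-expected heterozygosity, and the HWE test. How
identifying is that panel for one sample?

```r
fp  <- build_fingerprint(audit$genotypes, "S001", audit$summaries$probe_id)
rmp <- random_match_probability(fp, setNames(audit$summaries$maf,
                                             audit$summaries$probe_id))
#> log10 random-match probability for S001 over 206 loci: -86.1
```

A random unrelated individual matches S001's 206-locus profile with
probability 10^-86 — the profile is unique on any human scale. Redaction
removes the risk:

```r
red <- redact_probes(sim$beta, audit$summaries$probe_id)
#> redacted 206 probes; 3095 remain
nrow(select_informative_probes(red$matrix))
#> [1] 0
```

The same objects drive sample matching across datasets
(`match_samples(query, reference)`), smoking flagging at cg05575921
(`extract_trait_betas()` + `flag_trait_status()` — you must supply the
threshold), and in-silico MspI digest design to validate inferred genotypes
in the lab (`cpg_is_mspi_assayable()`, `predict_digest()`).

A command-line wrapper ships at
`system.file("cli", "methylaudit", package = "methylaudit")` with subcommands
`audit`, `match`, `redact`, `phi-report`, `mspi-design`, `simulate`.

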