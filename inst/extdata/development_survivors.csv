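group,family,category,count
variant,sex,male,13
variant,sex,female,10
control,sex,male,32
control,sex,female,31
variant,zygosity,heterozygote,21
variant,zygosity,homozygote,2
control,zygosity,heterozygote,42
control,zygosity,homozygote,21
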