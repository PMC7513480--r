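>sp01|sp01_s1
TGCCGCGACGCTCACGGCGCGGCCGCGCTTACGCGGCGTGGAAGCCACGCATAAGTTTTCCAAGGCTGGT
AGTACTTGCACATCCATCCCATTCAGTGTGCAGCCCTTCGGACGCCTCCT
>sp01|sp01_s2
TGCCGCGACGCTCACGGCGCGGCCACGCCTACGCGGCGTGGAAGCCACGCATCAGTTTTCCAAGGCTGGT
AGTACTTGGACATCCATCCCATTCAGCGTGCAGCCCTTCGGACGCCTCCT
>sp01|sp01_s3
TGCCGCGACGCTCACGGCGCAGCCGCGCCTACGCGGCGTGGAAGCAACGCATAAGTTTTCCAAGGCTGGT
AGTACTTGCACATCCATCCCATTCAGTGTACAGCCCTTCGGACGACTCCT
>sp02|sp02_s1
AGGCGCGACGCTCACGGCGCGGGCGCGCCTACTAGGCGTGGAGGCCACGCATAAGTTCACTAGGGCTGGT
AGTACTTGCACATGCATAGCATTCGGTGTGCAGCCCTTCGGTCGCCACCT
>sp02|sp02_s2
AGGCGCGACGCTCACGGCGCGGGCGCGCCTACTCGGCGTGGAGGCCACGCATAAGTTCACCGGGGCTCGT
AGTACTTGCACATGCATACCATTCGGTGTGCAGCCCTTCGGTCGCCACCT
>sp02|sp02_s3
AGGCGCGACGCTCACGGCGCGGGCGCGCCTACTCGGCGTGGAGGCCACGCATAAGTTCACCAGGGCTGGT
AGTACTTACACATGCATACCATTCGGTGTGCAGCCCTTCGGTCGTCACCT
>sp03|sp03_s1
TGCCGCGGCGCTCACGGCGCGGCCTCGCCTGCTCGGCGTGGAGGCCACGCGTAAGTTCGACAGGGCTGGT
AATACTTGGACATACATGCCATTCGGTGTGCAGCCCTTCGGACGCCGCAT
>sp03|sp03_s2
TGCCGCGGCGCTCACGGCGCGGCCTCGCCTGCTCGGCGTGGAGGCCACGCGTAAGTTCGCCAGGTCTGGT
AGTACTTAGATATACATACCATTCGGTGTGCAACCCTTCGGACGCCGCAT
>sp03|sp03_s3
TGCCGCGGCGCTCACGGCGCGGCCTCGCCTGCTCGACGTGGAAGCCACGCGTAAGTTCGCCAGGGCTGGT
AGTACTTGGACATACATACCATTCGGTGTGCAGCCCTTTGGACGCCGCAT
>sp04|sp04_s1
TGCCGCGACGCTCACGGCGCGGCCGCGCTTACTCAGCGTGGTGGCCACGCATAAATTCACCAGGGCTGGT
AGTACTTGCACATACATACCATTCGGTGTGCAGCCCTTCGGACGCCGACC
>sp04|sp04_s2
TGCCGCGACGCTAACGGCGCGGCCGCGCTTACTCAGCGTGGTGGCCACGCATAAATTCAGCAGGGCTGGT
AGTACTTGTGCATACATACCATTCGGTGTGCAGCCCTTCGGACGCCGACC
>sp04|sp04_s3
TGCCGCGACGCTCACGGCACGGCCGCGCTTACTCCGCGTGGTGGCCACGCATAAATTCACCAGGGCTGGT
AGTACTTGCACATACATACCATTCGGTGTGCAGCCCTTCGGACGCCGACC
>sp05|sp05_s1
TGCCGCGACGCTCATGGCGCGGCCGCGCCCACTGGGCGTGAAGGCTGCGCATAAGTTCAACAGGGCTGGT
AGTACTTGCTCATACATACCATTCGGTATGCAGCTCTTCGGACGTCGCCT
>sp05|sp05_s2
TGCCGCGACGCTCATGGCGCGGCCGCGCCCACTCGGCGTGAAGGCTGCGCATAAGTTCAACAGGGCTGGT
AGTACTTGCTCATACATACCATTCGGTGTGCAGCTCATCGGACGCCGCCT
>sp05|sp05_s3
TGCCGCGACGCTCATGGCGCGGCCGCGCCCACTCGGCGTGAAGGCTGCGCATAAGTTCAACAGGGCTGGT
AGTACTTGCTCATACATACCATTCGGTGTGCAGCTCTTCGGACGCCGCCC
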