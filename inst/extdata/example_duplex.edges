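target n1 n3
target n1 n11
target n1 n16
target n1 n17
target n1 n18
target n1 n25
target n2 n3
target n2 n8
target n2 n22
target n3 n13
target n3 n27
target n4 n14
target n4 n20
target n4 n24
target n4 n28
target n4 n29
target n4 n30
target n5 n10
target n5 n11
target n5 n14
target n5 n26
target n5 n27
target n5 n29
target n5 n30
target n6 n18
target n6 n20
target n6 n26
target n6 n29
target n7 n23
target n7 n24
target n7 n28
target n7 n29
target n8 n11
target n8 n15
target n8 n27
target n9 n10
target n9 n14
target n9 n17
target n9 n27
target n9 n30
target n10 n26
target n10 n30
target n11 n14
target n11 n19
target n12 n17
target n12 n21
target n12 n22
target n12 n29
target n12 n30
target n13 n15
target n13 n26
target n14 n29
target n15 n20
target n15 n28
target n15 n30
target n16 n19
target n16 n20
target n16 n24
target n17 n19
target n17 n25
target n18 n24
target n18 n26
target n18 n27
target n19 n20
target n19 n23
target n19 n28
target n20 n21
target n20 n22
target n20 n24
target n20 n25
target n20 n26
target n21 n22
target n21 n28
target n22 n26
target n22 n30
target n23 n26
target n23 n28
target n24 n27
target n24 n29
target n28 n29
aux n1 n11
aux n1 n12
aux n1 n18
aux n1 n25
aux n1 n27
aux n1 n29
aux n1 n30
aux n2 n3
aux n2 n8
aux n2 n14
aux n2 n16
aux n2 n24
aux n2 n25
aux n3 n6
aux n3 n27
aux n3 n28
aux n4 n14
aux n4 n20
aux n4 n24
aux n4 n28
aux n4 n29
aux n5 n7
aux n5 n10
aux n5 n25
aux n5 n26
aux n5 n27
aux n5 n30
aux n6 n18
aux n6 n19
aux n6 n26
aux n6 n29
aux n7 n21
aux n7 n23
aux n7 n24
aux n7 n28
aux n7 n29
aux n8 n11
aux n8 n15
aux n8 n25
aux n9 n10
aux n9 n23
aux n10 n26
aux n10 n28
aux n11 n14
aux n11 n19
aux n11 n21
aux n12 n14
aux n12 n29
aux n13 n15
aux n13 n24
aux n13 n26
aux n14 n28
aux n14 n29
aux n15 n20
aux n15 n29
aux n15 n30
aux n16 n19
aux n16 n24
aux n16 n30
aux n17 n24
aux n17 n25
aux n17 n27
aux n18 n22
aux n18 n26
aux n18 n27
aux n18 n30
aux n19 n20
aux n19 n21
aux n19 n26
aux n20 n22
aux n20 n24
aux n21 n22
aux n21 n26
aux n22 n26
aux n23 n26
aux n23 n28
aux n24 n27
aux n24 n29
aux n25 n28
aux n27 n29
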