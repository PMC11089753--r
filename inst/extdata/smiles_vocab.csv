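"character","code"
"(",1
"0",2
"1",3
"2",4
"3",5
"4",6
"5",7
"6",8
"7",9
"8",10
"9",11
"H",12
"A",13
"N",14
"B",15
"D",16
"E",17
"F",18
"G",19
"I",20
"K",21
"L",22
"M",23
"P",24
"R",25
"S",26
"T",27
"U",28
"V",29
"W",30
")",31
"Y",32
"Z",33
"a",34
"b",35
"c",36
"e",37
"g",38
"i",39
"=",40
"l",41
"C",42
"n",43
"o",44
"p",45
"r",46
"s",47
"O",48
"[",49
"]",50
"#",51
"+",52
"-",53
"/",54
"\",55
"@",56
"%",57
".",58
":",59
";",60
"~",61
"$",62
"{",63
"*",64
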