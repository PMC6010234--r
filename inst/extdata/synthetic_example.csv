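"respondent","order","response"
"resp001",1,"item009"
"resp001",2,"item008"
"resp001",3,"item001"
"resp001",4,"item018"
"resp001",5,"item006"
"resp001",6,"item007"
"resp001",7,"item021"
"resp001",8,"item017"
"resp001",9,"item002"
"resp001",10,"item004"
"resp001",11,"item013"
"resp001",12,"item005"
"resp002",1,"item001"
"resp002",2,"item006"
"resp002",3,"item005"
"resp002",4,"item014"
"resp002",5,"item004"
"resp002",6,"item025"
"resp002",7,"item030"
"resp002",8,"item019"
"resp002",9,"item003"
"resp002",10,"item007"
"resp003",1,"item009"
"resp003",2,"item001"
"resp003",3,"item013"
"resp003",4,"item006"
"resp003",5,"item004"
"resp003",6,"item019"
"resp003",7,"item003"
"resp003",8,"item002"
"resp004",1,"item010"
"resp004",2,"item001"
"resp004",3,"item003"
"resp004",4,"item004"
"resp004",5,"item011"
"resp004",6,"item002"
"resp004",7,"item022"
"resp004",8,"item014"
"resp005",1,"item037"
"resp005",2,"item002"
"resp005",3,"item001"
"resp005",4,"item027"
"resp005",5,"item011"
"resp005",6,"item031"
"resp005",7,"item014"
"resp005",8,"item003"
"resp005",9,"item021"
"resp005",10,"item005"
"resp005",11,"item022"
"resp005",12,"item012"
"resp005",13,"item039"
"resp006",1,"item006"
"resp006",2,"item002"
"resp006",3,"item012"
"resp006",4,"item001"
"resp006",5,"item011"
"resp006",6,"item005"
"resp006",7,"item027"
"resp006",8,"item004"
"resp006",9,"item003"
"resp006",10,"item010"
"resp006",11,"item030"
"resp006",12,"item007"
"resp006",13,"item023"
"resp006",14,"item032"
"resp007",1,"item001"
"resp007",2,"item006"
"resp007",3,"item030"
"resp007",4,"item024"
"resp007",5,"item003"
"resp007",6,"item009"
"resp007",7,"item004"
"resp007",8,"item036"
"resp007",9,"item002"
"resp007",10,"item027"
"resp008",1,"item001"
"resp008",2,"item015"
"resp008",3,"item002"
"resp008",4,"item012"
"resp008",5,"item025"
"resp008",6,"item036"
"resp008",7,"item040"
"resp008",8,"item008"
"resp009",1,"item001"
"resp009",2,"item002"
"resp009",3,"item009"
"resp009",4,"item021"
"resp009",5,"item017"
"resp010",1,"item011"
"resp010",2,"item001"
"resp010",3,"item002"
"resp010",4,"item014"
"resp010",5,"item029"
"resp011",1,"item002"
"resp011",2,"item001"
"resp011",3,"item009"
"resp011",4,"item015"
"resp012",1,"item040"
"resp012",2,"item005"
"resp012",3,"item002"
"resp012",4,"item009"
"resp012",5,"item003"
"resp012",6,"item004"
"resp012",7,"item007"
"resp012",8,"item032"
"resp012",9,"item001"
"resp012",10,"item025"
"resp013",1,"item004"
"resp013",2,"item001"
"resp013",3,"item002"
"resp013",4,"item012"
"resp013",5,"item005"
"resp013",6,"item003"
"resp013",7,"item026"
"resp013",8,"item030"
"resp013",9,"item007"
"resp013",10,"item028"
"resp013",11,"item027"
"resp013",12,"item006"
"resp014",1,"item008"
"resp014",2,"item006"
"resp014",3,"item003"
"resp014",4,"item025"
"resp014",5,"item014"
"resp014",6,"item004"
"resp014",7,"item021"
"resp014",8,"item002"
"resp014",9,"item013"
"resp015",1,"item003"
"resp015",2,"item001"
"resp016",1,"item017"
"resp016",2,"item006"
"resp016",3,"item001"
"resp016",4,"item033"
"resp016",5,"item004"
"resp016",6,"item019"
"resp016",7,"item003"
"resp016",8,"item040"
"resp017",1,"item014"
"resp017",2,"item013"
"resp017",3,"item010"
"resp017",4,"item001"
"resp017",5,"item002"
"resp017",6,"item003"
"resp018",1,"item001"
"resp018",2,"item002"
"resp018",3,"item003"
"resp018",4,"item004"
"resp018",5,"item013"
"resp018",6,"item012"
"resp018",7,"item031"
"resp018",8,"item034"
"resp018",9,"item039"
"resp018",10,"item005"
"resp019",1,"item010"
"resp019",2,"item001"
"resp019",3,"item025"
"resp019",4,"item002"
"resp020",1,"item006"
"resp020",2,"item003"
"resp020",3,"item001"
"resp020",4,"item026"
"resp021",1,"item009"
"resp021",2,"item026"
"resp021",3,"item003"
"resp021",4,"item005"
"resp021",5,"item025"
"resp021",6,"item004"
"resp021",7,"item001"
"resp021",8,"item024"
"resp021",9,"item002"
"resp021",10,"item007"
"resp021",11,"item006"
"resp021",12,"item019"
"resp021",13,"item034"
"resp022",1,"item005"
"resp022",2,"item001"
"resp022",3,"item027"
"resp022",4,"item008"
"resp022",5,"item036"
"resp022",6,"item003"
"resp022",7,"item010"
"resp022",8,"item002"
"resp022",9,"item006"
"resp023",1,"item036"
"resp023",2,"item002"
"resp023",3,"item013"
"resp023",4,"item031"
"resp023",5,"item004"
"resp023",6,"item001"
"resp023",7,"item025"
"resp023",8,"item034"
"resp023",9,"item008"
"resp023",10,"item003"
"resp023",11,"item010"
"resp023",12,"item012"
"resp023",13,"item005"
"resp024",1,"item001"
"resp024",2,"item006"
"resp024",3,"item023"
"resp024",4,"item003"
"resp024",5,"item022"
"resp024",6,"item010"
"resp024",7,"item002"
"resp024",8,"item005"
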